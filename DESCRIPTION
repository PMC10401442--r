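Package: gsoracle
Title: Stochastic Genomic-Selection Breeding-Program Simulation with
    Oracle Parental and Training-Population Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent genomic-selection breeding programs for
    inbred crop lines: meiosis with Haldane-model recombination, single-seed
    descent, additive quantitative trait loci with geometric effect series,
    multi-environment phenotypes at a target heritability, ridge-regression
    BLUP genomic prediction fitted by restricted maximum likelihood, and a
    suite of parental-selection strategies (truncation, scoping, chimeric
    scoping, oracle) and training-population update strategies (top, tails,
    random, PEVmean, CDmean, greedy oracle). Oracle strategies use the
    simulated ground truth to establish an upper bound against which
    practical marker-based strategies can be benchmarked for long-term
    genetic gain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
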