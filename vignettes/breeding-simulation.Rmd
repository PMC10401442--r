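---
title: "Simulating recurrent genomic-selection breeding programs with oracle benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating recurrent genomic-selection breeding programs with oracle benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsoracle)
```

## The problem

Genomic selection replaces phenotype-based parent choice with selection on
genome-wide estimated breeding values (GEBVs). Greedy truncation selection on
GEBVs yields fast short-term gain but erodes genetic variation, so favorable
alleles at weakly estimated loci are lost and the long-term genetic value
plateaus below its potential. Many remedies exist — diversity-aware parental
selection, smarter maintenance of the training population (TP) that feeds the
prediction model — but it is hard to say how far any of them is from the best
possible outcome.

`gsoracle` simulates a closed recurrent breeding program for an inbred crop
and, crucially, implements *oracle* strategies that peek at the simulated
ground truth: an oracle parental selector that knows the true QTLs and their
favorable alleles, and an oracle TP optimizer that greedily maximizes true
predictive performance. These define an upper bound ("utopia") against which
practical, marker-based strategies can be measured.

## The breeding scheme

Each cycle, `n_parents = 2 * n_couples` parents are selected from the current
breeding population and paired into couples; each couple produces
`offspring_per_couple` F1 offspring; two generations of single-seed descent
(one selfed seed per line per generation) then produce the next breeding
population. At the reference scale this is 100 parents, 50 couples, 20
offspring per couple, hence 1000 F1 and 1000 F3 individuals per cycle. The
first cycle crosses the phenotype rank-mates of the two founder subpopulations
(rank *i* of panel A with rank *i* of panel B); all later cycles select on
GEBVs (or on the oracle's ground truth).

Within one cycle the event order is: (1) TP update (new entries are
phenotyped) and model refit, (2) GEBV prediction for the breeding population,
(3) parental selection and coupling, (4) crossing, (5) single-seed descent,
(6) metric collection. The top/tails/random TP update is driven by the
previous cycle's model, after which the model is refit before selection — the
scheme never phenotypes the breeding population at large.

## Genome, QTL model and meiosis

Founders are fully inbred lines carrying biallelic loci (alleles 0/1) on a
multi-chromosome genetic map; genotype dosage is `h1 + h2 - 1`, i.e. -1/0/+1.
Of the available loci, `L` (default 100) are drawn uniformly at random as
QTLs; the rest are the markers used for prediction. QTL effects follow a
geometric series: the k-th QTL contributes `+a^k` for the favorable
homozygote, 0 for the heterozygote and `-a^k` for the unfavorable homozygote,
with `a = (L-1)/(L+1)`, no dominance and no epistasis. The series order is a
uniform random permutation of the chosen loci, and the favorable allele is
assigned uniformly at random per QTL — this lets favorable alleles be rare,
which is what makes their loss under greedy selection possible. The *maximum
reachable genetic value* sums the signed effects of fixed QTLs plus the
favorable effects of segregating QTLs; rescaled by the ideal-genotype value,
it equals 1 while nothing unfavorable is fixed. Because no mutation is
modeled, fixation is irreversible: the rescaled maximum reachable value never
increases, and the effect mass still segregating never grows.

Meiosis uses the standard count-location model with Haldane mapping: per
chromosome, the crossover count is Poisson with mean the map length in
Morgans, crossover positions are uniform, there is no interference, and the
starting haplotype is chosen with probability 1/2. The tests verify the
recombinant fraction against Haldane's closed form `(1 - exp(-2d/100))/2`.

## Phenotypes

Phenotyping happens in `n_env = 3` environments. Line *i* in environment *j*
has value `y_ij = g_i + e_j + eps_ij` with `e_j ~ N(0, sigmaE2)` shared by the
whole batch and `eps_ij ~ N(0, sigmaR2)` independent; the recorded phenotype
is the mean over environments. The components are frozen before the first
cycle from the genetic variance `var(g)` of the pre-cycle-1 breeding
population: `sigmaE2 = 8 var(g)` and `sigmaR2 = 3 (var(g)/h2 - var(g))`, which
realizes a narrow-sense heritability of `h2 = 0.5` on the environment-mean
phenotype (the shared environment effect shifts a whole batch and cancels
from within-batch comparisons; the `h2` denominator is `var(g) + sigmaR2/3`).
Both components stay fixed for the entire simulation. Environment effects are
redrawn for every phenotyping batch, so no single environment draw is
confounded with a cycle. Whether `var(g)` refers to the founders or to the
first F3 population is ambiguous in the protocol this package follows; the
cycle-1 F3 population is the default (`var_g_reference = "f3"`), with a
founder-based switch.

## Genomic prediction

GEBVs come from ridge-regression BLUP: `y = 1 beta + Z u + eps` with
`u ~ N(0, sigma_u2 I_k)` over all markers (monomorphic ones included; the
ridge system is full rank for `lambda > 0`). The restricted likelihood is
profiled down to `lambda = sigma_e2/sigma_u2` via one spectral decomposition
of the intercept-projected marker kernel `Z Z'`, and maximized by bounded
scalar search over `log lambda` in `[-10, 10]` (tolerance 1e-8; a boundary
optimum is flagged). GEBVs are `Z u_hat` without the intercept — rankings are
invariant to it. PEVmean and CDmean updates score candidates by the
prediction error variance (or reliability `CD = 1 - PEV/(sigma_u2 c'c)`) of
the contrast between a candidate's GEBV and the TP mean, computed through the
absorbed mixed-model equations; the contrast convention is recorded here
because the criteria are named but their contrast construction is a design
choice.

## Parental selection strategies

* **Truncation**: the `n_parents` highest GEBVs, paired at random.
* **Scoping**: preselect the top `ceiling(SR * n)` by GEBV (`SR = 0.3` is the
  reference rate); then build couples sequentially — P1 is the best
  remaining GEBV, P2 maximizes the F-score, the sum over markers of the
  dosage-column variance of the already-selected parents plus the candidate,
  masked by a Boolean vector `p` that tracks markers still missing one
  allele (reset to all ones when exhausted). The candidate is provisionally
  included in the variance computation, since the F-score of the selected
  set alone would not depend on the candidate.
* **Chimeric scoping**: the first `N` couples follow scoping; the remaining
  couples pick both parents purely as F-score maximizers from the whole
  population, sharing the mask and selected set. The schedule of `N` over
  cycles is configuration (`chimeric_ramp` breakpoints), as no canonical
  ramp exists.
* **Oracle parental selection**: scores each individual by the number of
  QTLs at which it carries at least one favorable allele (heterozygotes
  count as carriers), restricted to QTLs whose favorable allele is missing
  from the parents selected so far; when every favorable allele is covered,
  all QTLs count. Ties break by ascending id everywhere, for cross-platform
  reproducibility.

Parents are distinct within a crossing block (an individual parents at most
one couple).

## Training-population maintenance

The reference (non-oracle) protocol starts from the full base population,
drops the 150 oldest TP members each cycle and adds 150 by the *tails* rule
(75 highest + 75 lowest GEBVs). The oracle TP protocol starts from 100 random
base individuals and may add and remove up to 50 individuals per cycle: each
greedy iteration evaluates every possible addition (then every possible
removal) by the Pearson correlation between GEBVs and true genetic values
over the evaluation set — the breeding population minus everyone accepted
into the TP this cycle — and accepts only strict improvements (tolerance
1e-10, preventing tie cycling). Removal candidates exclude this cycle's
additions, so nothing is added and removed in the same cycle. Candidate
refits reuse the current `lambda` with exact rank-one block-inverse updates
of the kernel system (one matrix multiply scores a whole sweep); `lambda` is
re-estimated by full REML at loop start and after every 10 accepted changes,
since it is insensitive to single-row changes — `refit_every = 1` restores
the audit mode that refits at every step. The add and remove phases alternate
once each per iteration.

## Metrics

Per cycle the engine records: mean rescaled genetic value of the top-10
individuals (the prime commercialization candidates) and of the whole
population; the rescaled maximum reachable and fixed genetic values;
predictive performance (Pearson correlation of GEBVs with true genetic
values over the breeding population); the mean genomic relationship between
TP and population; the mean absolute residual error `|g - y|` of this
cycle's TP additions; and TP bookkeeping. The relationship uses the
allele-frequency-centered cross product `G = M M' / (2 sum P_i (1 - P_i))`
with base-population frequencies. One numerical point deserves note: when
`P_i` is estimated from the base population itself, the cross-block mean of
`G` over the base is exactly zero (the centering annihilates it), so it
cannot serve as a scaling reference. The engine therefore scales TP-population
relationship means by the mean *self*-relationship (diagonal of `G`) of the
base population, which is positive and stable.

## Synthetic founders

The generator emulates the structure the simulator assumes about its input
panels: two subpopulations of fully inbred lines (sizes 384 and 380 by
default), ~1590 biallelic loci on 7 chromosomes (a barley-like karyotype),
along-chromosome linkage disequilibrium, a fraction of loci already fixed in
the union population (default 0.05, so the initial rescaled maximum reachable
value sits just below 1), and founder phenotypes at heritability 0.5 from a
provisional additive model that is independent of the QTL model later drawn
for the simulation. Haplotypes come from a latent Gaussian AR(1) process
along each chromosome — adjacent-locus latent correlation `ld_decay^d` for a
gap of `d` cM — thresholded at group-specific allele frequencies that diverge
from the shared base frequency by a beta drift (`fst`, default 0.05). Map
lengths default to 7 x 150 cM with uniform marker spacing; these are explicit
configuration, not claims about any real map, which the source panels do not
publish. What the generator does *not* emulate: realistic site-frequency
spectra, mutation, genotyping error, missing data, and LD between
chromosomes; passing tests on synthetic founders therefore validate the
machinery and the qualitative method ordering, not quantitative predictions
for any particular crop panel.

## Numerical choices and degenerate inputs

* Tie-breaking is stable ascending id in every selector and update rule.
* Population-denominator variances are used for the F-score and for the
  frozen `var(g)` (they are population parameters, not sample estimates).
* REML boundary optima are flagged rather than errored; zero-variance
  phenotypes are an error.
* A degenerate oracle evaluation set (fewer than 3 individuals, or constant
  true values) scores as `-Inf` so it can never win an acceptance
  comparison, and is logged as a warning.
* Heterozygous genotype calls read from files are stored phase-unknown;
  generated founders are exactly homozygous.
* Missing genotype calls are rejected at read time; the pipeline assumes
  complete data.

## A small worked experiment

The reference scale (1000 individuals x 50 cycles x 100 runs) is a cluster
workload. The package's own tests exercise a reduced standard scale chosen to
preserve the protocol's proportions rather than its absolute sizes: 200
individuals per cycle (10 couples x 20 offspring, 20 parents — the reference
10% selected fraction), QTLs scaled with the parent count (L = 20, keeping
the 1:1 QTL:parent ratio that shapes the oracle's coverage phase), markers at
~15 per QTL (320 loci), 150 synthetic founders (75 per panel, the reference
3:4 founder:population ratio), tails TP update adding 30 and dropping the 30
oldest (15% of the population, as in the reference protocol), 20 cycles for
parental-method comparisons and 15 for TP-method comparisons, 10 paired
runs. Keeping these ratios matters: for instance, raising L well above the
parent count makes the oracle's allele-coverage phase consume most of the
crossing block, which the reference protocol never does.

```{r example, eval = FALSE}
cfg <- experiment_config(
  founders = list(n_per_group = c(75, 75), n_loci = 320, n_chromosomes = 7,
                  ld_decay = 0.9),
  L = 20, n_couples = 10, offspring_per_couple = 20,
  n_cycles = 20, n_runs = 10,
  tp = list(protocol = "standard", method = "tails",
            n_add = 30, n_drop_oldest = 30),
  seed = 1)
cmp <- compare_methods(cfg, list(
  truncation = list(selection = list(method = "truncation")),
  scoping    = list(selection = list(method = "scoping", SR = 0.3)),
  oracle     = list(selection = list(method = "oracle"))))
aggregate(top10_value ~ method, cmp[cmp$cycle == 20, ], mean)
```

## Known limitations

* The OGM parental selector, the TrainSel genetic-algorithm TP optimizer and
  deep scoping's genebank layers are external methods and are not
  implemented; the engine's method dispatch is the plug-in point for them.
* Single trait, purely additive architecture; no genotype-by-environment
  interaction; no mutation or migration, so diversity only ever decreases.
* The oracle TP optimizer's greedy search is exact per step but not a global
  optimum over TP subsets.
* Reduced-scale runs reproduce the *ordering* of methods; the sizes of the
  full-scale gaps depend on population size, marker density and cycle count
  and are not reproduced at desk scale.
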