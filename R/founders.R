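#' Founder set
#'
#' Bundles the founder haplotypes, their phenotypes and their subpopulation
#' labels. Generated founders are fully inbred (identical haplotype pairs);
#' founders read from real data may carry residual heterozygosity, which is
#' stored phase-unknown.
#'
#' @param haplotypes a [haplo_pop()].
#' @param phenotypes numeric vector, one trait value per individual.
#' @param group character/factor subpopulation label per individual.
#' @return An object of class `founder_set`.
#' @export
founder_set <- function(haplotypes, phenotypes, group) {
  n <- n_ind(haplotypes)
  if (length(phenotypes) != n || length(group) != n)
    stop("phenotypes and group must have one entry per individual")
  if (anyNA(phenotypes)) stop("missing phenotype value")
  structure(list(haplotypes = haplotypes,
                 phenotypes = as.numeric(phenotypes),
                 group = as.character(group)),
            class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  tab <- table(x$group)
  cat("Founder set:", n_ind(x$haplotypes), "individuals (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      ") x", n_loci(x$haplotypes$map), "loci\n")
  invisible(x)
}

fail_file <- function(path, line, msg) {
  stop(sprintf("%s (file '%s', line %d)", msg, path, line), call. = FALSE)
}

read_genotype_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) fail_file(path, 1L, "genotype file needs a header and at least one individual")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) && header[1L] %in% c("", "id")) header <- header[-1L]
  locus_ids <- header
  k <- length(locus_ids)
  n <- length(lines) - 1L
  geno <- matrix(NA_integer_, n, k)
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(f) != k + 1L)
      fail_file(path, i + 1L, sprintf("expected %d fields, found %d", k + 1L, length(f)))
    ids[i] <- f[1L]
    v <- suppressWarnings(as.integer(f[-1L]))
    if (anyNA(v)) fail_file(path, i + 1L, "non-integer genotype dosage")
    if (any(v < -1L | v > 1L))
      fail_file(path, i + 1L, "genotype dosage outside {-1, 0, 1}: non-biallelic or miscoded locus")
    geno[i, ] <- v
  }
  if (anyDuplicated(ids)) fail_file(path, which(duplicated(ids))[1L] + 1L, "duplicated individual id")
  list(ids = ids, locus_ids = locus_ids, geno = geno)
}

read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF genotypes requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- cbind(vcfR::getREF(v), vcfR::getALT(v))
  if (any(is.na(alleles)) || any(nchar(alleles) != 1L) || any(grepl(",", alleles[, 2L])))
    stop(sprintf("non-biallelic locus in VCF '%s'", path), call. = FALSE)
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- -1L
    out[g %in% c("0/1", "1/0")] <- 0L
    out[g %in% "1/1"] <- 1L
    out
  }
  geno <- t(apply(gt, 2L, code))
  if (anyNA(geno)) stop(sprintf("missing or unsupported GT call in VCF '%s'", path), call. = FALSE)
  ids <- colnames(gt)
  locus_ids <- vcfR::getID(v)
  if (anyNA(locus_ids)) locus_ids <- paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v))
  list(ids = ids, locus_ids = locus_ids, geno = geno)
}

#' Read founder data from delimited files
#'
#' Reads a founder population from a genotype matrix (TSV, or VCF when the
#' file name ends in `.vcf`/`.vcf.gz`), a genetic map TSV with columns
#' `locus_id`, `chromosome`, `position_cM`, and a phenotype TSV with columns
#' `individual_id`, `phenotype`, `group`. Genotype dosages are coded -1/0/1;
#' heterozygous calls are stored phase-unknown. Individuals without a
#' phenotype record are rejected (dropped with a warning); missing genotype
#' calls are not supported.
#'
#' @param genotype_path path to the genotype TSV (or VCF).
#' @param map_path path to the map TSV.
#' @param phenotype_path path to the phenotype TSV.
#' @return a [founder_set()].
#' @export
read_founders <- function(genotype_path, map_path, phenotype_path) {
  g <- if (grepl("\\.vcf(\\.gz)?$", genotype_path)) read_genotype_vcf(genotype_path)
       else read_genotype_tsv(genotype_path)

  m <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  need <- c("locus_id", "chromosome", "position_cM")
  if (!all(need %in% names(m)))
    stop(sprintf("map file '%s' must have columns %s", map_path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (length(g$locus_ids) != nrow(m))
    stop(sprintf("dimension mismatch: %d loci in '%s' but %d in map '%s'",
                 length(g$locus_ids), genotype_path, nrow(m), map_path), call. = FALSE)
  unknown <- setdiff(g$locus_ids, m$locus_id)
  if (length(unknown))
    stop(sprintf("unknown locus id '%s' in '%s' (absent from map '%s')",
                 unknown[1L], genotype_path, map_path), call. = FALSE)
  map <- genetic_map(m$locus_id, m$chromosome, m$position_cM)
  # reorder genotype columns to map order
  geno <- g$geno[, match(map$locus_id, g$locus_ids), drop = FALSE]

  ph <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE)
  need <- c("individual_id", "phenotype", "group")
  if (!all(need %in% names(ph)))
    stop(sprintf("phenotype file '%s' must have columns %s", phenotype_path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!is.numeric(ph$phenotype)) {
    bad <- which(is.na(suppressWarnings(as.numeric(ph$phenotype))))[1L]
    fail_file(phenotype_path, bad + 1L, "non-numeric phenotype")
  }
  keep <- g$ids %in% ph$individual_id
  if (!all(keep)) {
    warning(sum(!keep), " individual(s) without a phenotype record rejected")
    geno <- geno[keep, , drop = FALSE]
  }
  ids <- g$ids[keep]
  ph <- ph[match(ids, ph$individual_id), , drop = FALSE]

  hap1 <- (geno >= 0L) * 1L   # het coded (0,1), phase unknown
  hap2 <- (geno > 0L) * 1L
  founder_set(haplo_pop(hap1, hap2, map, ids), ph$phenotype, ph$group)
}

#' Write a founder set to delimited files
#'
#' Inverse of [read_founders()]: writes the genotype, map and phenotype TSV
#' files in the dialects that function reads.
#'
#' @param founders a `founder_set`.
#' @param genotype_path,map_path,phenotype_path output paths.
#' @return invisibly, the three paths.
#' @export
write_founders <- function(founders, genotype_path, map_path, phenotype_path) {
  pop <- founders$haplotypes
  map <- pop$map
  geno <- dosages(pop)
  lines <- c(paste(c("id", map$locus_id), collapse = "\t"),
             vapply(seq_len(nrow(geno)), function(i)
               paste(c(pop$ids[i], geno[i, ]), collapse = "\t"), character(1)))
  writeLines(lines, genotype_path)
  utils::write.table(
    data.frame(locus_id = map$locus_id, chromosome = map$chromosome,
               position_cM = map$pos_cM),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(individual_id = pop$ids, phenotype = founders$phenotypes,
               group = founders$group),
    phenotype_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genotype_path, map_path, phenotype_path))
}

#' Generate a synthetic founder population
#'
#' Emulates the structure of a pair of elite inbred panels: two
#' subpopulations of fully homozygous lines genotyped at biallelic loci on a
#' multi-chromosome map, with linkage disequilibrium decaying along each
#' chromosome, a fraction of loci already fixed in the union population, and
#' phenotypes at a target heritability.
#'
#' Each line's single founder haplotype is generated from a latent Gaussian
#' first-order autoregressive process along the chromosome: the correlation
#' between the latent values of adjacent loci d cM apart is `ld_decay^d`,
#' and the latent value is thresholded at the group-specific allele
#' frequency. Group frequencies diverge from the shared base frequency by a
#' beta-distributed drift controlled by `fst`. Phenotypes come from a
#' provisional additive model (independent of any QTL model later built on
#' these founders) plus Gaussian noise scaled to heritability `h2`.
#'
#' @param n_per_group integer pair: lines per subpopulation (default the
#'   two-panel sizes 384 and 380).
#' @param n_loci total biallelic locus count (default 1590).
#' @param n_chromosomes chromosome count (default 7, as in barley).
#' @param ld_decay per-cM correlation of the latent process, in \[0, 1\].
#' @param maf_floor minimum base allele frequency for segregating loci.
#' @param fixed_frac fraction of loci fixed in the union population.
#' @param fst drift parameter controlling group-level frequency divergence.
#' @param h2 heritability of the founder phenotypes.
#' @param chrom_length_cM chromosome length in centimorgans.
#' @param seed optional integer seed (sets the global RNG).
#' @return a [founder_set()].
#' @export
generate_synthetic_founders <- function(n_per_group = c(384L, 380L),
                                        n_loci = 1590L, n_chromosomes = 7L,
                                        ld_decay = 0.9, maf_floor = 0.05,
                                        fixed_frac = 0.05, fst = 0.05,
                                        h2 = 0.5, chrom_length_cM = 150,
                                        seed = NULL) {
  if (length(n_per_group) != 2L || any(n_per_group < 1L))
    stop("n_per_group must be a pair of positive counts")
  if (n_loci < n_chromosomes) stop("n_loci must be >= n_chromosomes")
  if (ld_decay < 0 || ld_decay > 1) stop("ld_decay must be in [0, 1]")
  if (maf_floor < 0 || maf_floor >= 0.5) stop("maf_floor must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)

  map <- uniform_map(n_loci, n_chromosomes, chrom_length_cM)
  n_total <- sum(n_per_group)
  group <- rep(c("A", "B"), n_per_group)

  base_f <- stats::runif(n_loci, maf_floor, 1 - maf_floor)
  n_fixed <- floor(fixed_frac * n_loci)
  fixed_idx <- if (n_fixed > 0) sample.int(n_loci, n_fixed) else integer(0)
  base_f[fixed_idx] <- sample(c(0, 1), n_fixed, replace = TRUE)

  # group-level frequencies: beta drift around the base frequency
  gfreq <- matrix(rep(base_f, 2L), nrow = 2L, byrow = TRUE)
  if (fst > 0) {
    seg <- setdiff(seq_len(n_loci), fixed_idx)
    c0 <- (1 - fst) / fst
    for (gi in 1:2)
      gfreq[gi, seg] <- stats::rbeta(length(seg), base_f[seg] * c0,
                                     (1 - base_f[seg]) * c0)
  }

  hap <- matrix(0L, n_total, n_loci)
  for (chr in map_chromosomes(map)) {
    m <- length(chr$idx)
    phi <- if (m > 1) ld_decay^diff(chr$pos) else numeric(0)
    x <- matrix(0, n_total, m)
    x[, 1L] <- stats::rnorm(n_total)
    if (m > 1) for (j in 2:m)
      x[, j] <- phi[j - 1L] * x[, j - 1L] +
        sqrt(1 - phi[j - 1L]^2) * stats::rnorm(n_total)
    thr <- stats::qnorm(pmin(pmax(gfreq, 1e-12), 1 - 1e-12))
    for (gi in 1:2) {
      rows <- which(group == c("A", "B")[gi])
      hap[rows, chr$idx] <- (x[rows, , drop = FALSE] <
                               matrix(thr[gi, chr$idx], length(rows), m,
                                      byrow = TRUE)) * 1L
    }
  }
  # enforce union-level fixation exactly
  if (n_fixed > 0)
    hap[, fixed_idx] <- matrix(rep(as.integer(base_f[fixed_idx]), each = n_total),
                               n_total, n_fixed)

  ids <- sprintf("%s%04d", group, unlist(lapply(n_per_group, seq_len)))
  pop <- haplo_pop(hap, hap, map, ids)

  # provisional additive model for founder phenotypes (not the simulation QTLs)
  Lp <- max(2L, min(100L, n_loci %/% 4L))
  a <- (Lp - 1) / (Lp + 1)
  prov_loci <- sample.int(n_loci, Lp)
  eff <- a^seq_len(Lp) * sample(c(-1, 1), Lp, replace = TRUE)
  g <- as.numeric(dosages(pop, prov_loci) %*% eff)
  vg <- stats::var(g)
  noise_sd <- if (vg > 0) sqrt(vg * (1 / h2 - 1)) else 1
  y <- g + stats::rnorm(n_total, 0, noise_sd)
  founder_set(pop, y, group)
}
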