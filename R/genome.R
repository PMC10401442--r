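#' Additive QTL model with geometric effect series
#'
#' Draws `L` quantitative trait loci uniformly without replacement from the
#' loci of the founder map and assigns them a geometric series of additive
#' effects: the k-th QTL contributes `a^k` for the favorable homozygote, 0
#' for the heterozygote and `-a^k` for the unfavorable homozygote, with
#' `a = (L - 1) / (L + 1)`. The ordering of loci along the series is a
#' uniform random permutation of the chosen loci and the favorable allele is
#' assigned uniformly at random per QTL. Dominance and epistasis are absent.
#' The remaining loci become the markers used for genomic prediction.
#'
#' @param founders a [founder_set()] (only its map/locus count is used).
#' @param L number of QTLs; must be smaller than the locus count.
#' @param seed optional integer seed (sets the global RNG).
#' @return An object of class `qtl_model` with fields `qtl_idx` (locus
#'   indices in series order), `favorable` (0/1 favorable allele per QTL),
#'   `effects` (`a^k`), `marker_idx`, `a`, `L` and `denom`
#'   (`sum(effects)`, the genetic value of the ideal genotype, used for
#'   rescaling to 1).
#' @export
build_qtl_model <- function(founders, L, seed = NULL) {
  m <- n_loci(founders$haplotypes$map)
  if (L >= m) stop("L must be smaller than the locus count (", m, ")")
  if (L < 1L) stop("L must be positive")
  if (!is.null(seed)) set.seed(seed)
  qtl_idx <- sample.int(m, L)        # draw + permutation in one step
  a <- (L - 1) / (L + 1)
  effects <- a^seq_len(L)
  favorable <- sample(0:1, L, replace = TRUE)
  structure(list(qtl_idx = qtl_idx, favorable = favorable, effects = effects,
                 marker_idx = setdiff(seq_len(m), qtl_idx),
                 a = a, L = L, denom = sum(effects)),
            class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat("QTL model: L =", x$L, "QTLs (a =", format(x$a, digits = 4),
      "),", length(x$marker_idx), "markers; ideal value", format(x$denom, digits = 4), "\n")
  invisible(x)
}

# signed dosage at QTLs: +1 favorable homozygote, 0 het, -1 unfavorable (internal)
signed_qtl_dosage <- function(qtl_geno, model) {
  sweep(qtl_geno, 2L, 2 * model$favorable - 1, `*`)
}

#' True genetic values
#'
#' Sum over QTLs of the signed geometric effect: `+a^k` for the favorable
#' homozygote, 0 for the heterozygote, `-a^k` for the unfavorable
#' homozygote (purely additive).
#'
#' @param qtl_geno dosage matrix (individuals x QTLs) with columns aligned
#'   to `model$qtl_idx`, or a `haplo_pop` from which QTL dosages are taken.
#' @param model a `qtl_model`.
#' @param rescaled divide by the ideal-genotype value so the maximum is 1?
#' @return numeric vector of genetic values.
#' @export
genetic_value <- function(qtl_geno, model, rescaled = FALSE) {
  if (inherits(qtl_geno, "haplo_pop")) qtl_geno <- dosages(qtl_geno, model$qtl_idx)
  if (ncol(qtl_geno) != model$L)
    stop("QTL genotype matrix has ", ncol(qtl_geno), " columns; expected ", model$L)
  g <- as.numeric(signed_qtl_dosage(qtl_geno, model) %*% model$effects)
  if (rescaled) g / model$denom else g
}

# fixation status of each QTL in a population: +1 fixed favorable,
# -1 fixed unfavorable, NA segregating (internal)
qtl_fixation <- function(population, model) {
  d <- dosages(population, model$qtl_idx)
  s <- signed_qtl_dosage(d, model)
  lo <- apply(s, 2L, min); hi <- apply(s, 2L, max)
  out <- rep(NA_real_, model$L)
  out[lo == 1] <- 1; out[hi == -1] <- -1
  out
}

#' Maximum reachable genetic value
#'
#' The best genetic value still attainable by the population given which QTL
#' alleles are already fixed: the signed value of every fixed QTL plus the
#' favorable value of every still-segregating QTL. When no unfavorable
#' allele is fixed the rescaled value is exactly 1.
#'
#' @param population a `haplo_pop` (the current breeding population).
#' @param model a `qtl_model`.
#' @param rescaled divide by the ideal-genotype value?
#' @return a single numeric value.
#' @export
max_reachable_value <- function(population, model, rescaled = TRUE) {
  if (n_ind(population) == 0L) stop("empty population")
  fx <- qtl_fixation(population, model)
  contrib <- ifelse(is.na(fx), 1, fx) * model$effects
  v <- sum(contrib)
  if (rescaled) v / model$denom else v
}

#' Fixed genetic value
#'
#' The signed sum of effects over QTLs fixed in the population: the part of
#' the genetic value that selection can no longer change.
#'
#' @inheritParams max_reachable_value
#' @return a single numeric value.
#' @export
fixed_genetic_value <- function(population, model, rescaled = TRUE) {
  if (n_ind(population) == 0L) stop("empty population")
  fx <- qtl_fixation(population, model)
  v <- sum(ifelse(is.na(fx), 0, fx) * model$effects)
  if (rescaled) v / model$denom else v
}

# one gamete for one chromosome: Poisson crossover count (Haldane, no
# interference), uniform crossover positions, random starting haplotype
gamete_chrom <- function(h1, h2, pos, len_cM) {
  n_xo <- stats::rpois(1L, len_cM / 100)
  start <- stats::runif(1L) < 0.5
  if (n_xo == 0L) return(if (start) h1 else h2)
  xo <- sort(stats::runif(n_xo, pos[1L], pos[1L] + len_cM))
  seg <- findInterval(pos, xo) + start        # parity picks the haplotype
  ifelse(seg %% 2L == 1L, h1, h2)
}

#' Simulate one gamete
#'
#' Meiosis under the Haldane model: per chromosome the crossover count is
#' Poisson with mean the map length in Morgans, crossover positions are
#' uniform along the chromosome, there is no interference, and the starting
#' parental haplotype is chosen with probability 1/2. Chromosomes segregate
#' independently. Uses the current global RNG stream.
#'
#' @param pop a `haplo_pop`.
#' @param i index of the parent individual.
#' @return integer vector of 0/1 alleles over all loci.
#' @export
make_gamete <- function(pop, i) {
  h1 <- pop$hap1[i, ]; h2 <- pop$hap2[i, ]
  out <- h1
  for (chr in .chrom_cache(pop$map)) {
    idx <- chr$idx
    out[idx] <- gamete_chrom(h1[idx], h2[idx], chr$pos, chr$len)
  }
  out
}

# per-map chromosome layout cache (maps are small and few; keyed by identity
# of positions, cheap enough to recompute when not cached)
.chrom_env <- new.env(parent = emptyenv())
.chrom_cache <- function(map) {
  key <- paste0(nrow(map), "_", map$chromosome[1L], "_",
                format(sum(map$pos_cM), digits = 15))
  got <- .chrom_env[[key]]
  if (!is.null(got)) return(got)
  chrs <- lapply(map_chromosomes(map), function(ch) {
    ch$len <- max(ch$pos) - min(ch$pos)
    ch
  })
  .chrom_env[[key]] <- chrs
  chrs
}

#' Cross parent couples
#'
#' Each couple produces `n_offspring` offspring; every offspring receives
#' one independently simulated gamete from each parent.
#'
#' @param pop a `haplo_pop` containing the parents.
#' @param couples two-column matrix (or data frame) of parent indices or
#'   ids, one row per couple.
#' @param n_offspring offspring per couple.
#' @param ids optional character vector of offspring ids (default
#'   `F1_<n>`).
#' @return a `haplo_pop` of `nrow(couples) * n_offspring` F1 individuals.
#' @export
cross <- function(pop, couples, n_offspring, ids = NULL) {
  couples <- as.matrix(couples)
  if (is.character(couples)) {
    couples <- matrix(match(couples, pop$ids), ncol = 2L)
    if (anyNA(couples)) stop("unknown parent id in couples")
  }
  n_out <- nrow(couples) * n_offspring
  m <- n_loci(pop$map)
  hap1 <- matrix(0L, n_out, m); hap2 <- matrix(0L, n_out, m)
  r <- 0L
  for (ci in seq_len(nrow(couples))) {
    p1 <- couples[ci, 1L]; p2 <- couples[ci, 2L]
    for (o in seq_len(n_offspring)) {
      r <- r + 1L
      hap1[r, ] <- make_gamete(pop, p1)
      hap2[r, ] <- make_gamete(pop, p2)
    }
  }
  if (is.null(ids)) ids <- sprintf("F1_%05d", seq_len(n_out))
  haplo_pop(hap1, hap2, pop$map, ids)
}

#' Single-seed descent
#'
#' Advances every individual by `generations` rounds of selfing, keeping a
#' single selfed descendant per line per generation (two independent gametes
#' from the same individual). Population size is preserved; heterozygosity
#' halves in expectation each generation.
#'
#' @param pop a `haplo_pop`.
#' @param generations number of selfing generations.
#' @param ids optional ids for the final generation (defaults to the input
#'   ids, since each line is the direct descendant of one input line).
#' @return a `haplo_pop` of the same size.
#' @export
single_seed_descent <- function(pop, generations, ids = NULL) {
  for (g in seq_len(generations)) {
    n <- n_ind(pop)
    m <- n_loci(pop$map)
    hap1 <- matrix(0L, n, m); hap2 <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      hap1[i, ] <- make_gamete(pop, i)
      hap2[i, ] <- make_gamete(pop, i)
    }
    pop <- haplo_pop(hap1, hap2, pop$map, pop$ids)
  }
  if (!is.null(ids)) pop$ids <- as.character(ids)
  pop
}
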