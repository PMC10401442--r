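#' Haplotype population
#'
#' Container for a set of diploid individuals carrying phased biallelic
#' haplotype pairs over the loci of a genetic map. Alleles are coded 0/1;
#' the genotype dosage at a locus is `h1 + h2 - 1`, in \{-1, 0, 1\}, so that
#' fully inbred lines carry -1 or 1 and heterozygotes 0.
#'
#' @param hap1,hap2 integer matrices (individuals x loci) of 0/1 alleles.
#' @param map a [genetic_map()] with as many loci as the matrices have columns.
#' @param ids character vector of unique individual identifiers.
#'
#' @return An object of class `haplo_pop`.
#' @export
haplo_pop <- function(hap1, hap2, map, ids) {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  if (!identical(dim(hap1), dim(hap2)))
    stop("hap1 and hap2 must have identical dimensions")
  if (ncol(hap1) != n_loci(map))
    stop("haplotype length (", ncol(hap1), ") != locus count (", n_loci(map), ")")
  if (nrow(hap1) != length(ids)) stop("one id required per individual")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated individual ids")
  if (length(hap1) && (any(hap1 < 0L | hap1 > 1L) || any(hap2 < 0L | hap2 > 1L)))
    stop("haplotype alleles must be 0 or 1")
  dimnames(hap1) <- dimnames(hap2) <- NULL
  structure(list(hap1 = hap1, hap2 = hap2, map = map, ids = ids),
            class = "haplo_pop")
}

#' @export
print.haplo_pop <- function(x, ...) {
  cat("Haplotype population:", n_ind(x), "individuals x", n_loci(x$map),
      "loci\n")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `haplo_pop`.
#' @return integer.
#' @export
n_ind <- function(pop) nrow(pop$hap1)

#' Genotype dosage matrix
#'
#' @param pop a `haplo_pop`.
#' @param loci optional integer vector of locus columns to extract.
#' @return integer matrix (individuals x loci) with entries in \{-1, 0, 1\}.
#' @export
dosages <- function(pop, loci = NULL) {
  if (is.null(loci)) d <- pop$hap1 + pop$hap2 - 1L
  else d <- pop$hap1[, loci, drop = FALSE] + pop$hap2[, loci, drop = FALSE] - 1L
  rownames(d) <- pop$ids
  d
}

#' Subset a population by individual
#' @param pop a `haplo_pop`.
#' @param i integer or character index of individuals to keep.
#' @return a `haplo_pop`.
#' @export
subset_pop <- function(pop, i) {
  if (is.character(i)) i <- match(i, pop$ids)
  haplo_pop(pop$hap1[i, , drop = FALSE], pop$hap2[i, , drop = FALSE],
            pop$map, pop$ids[i])
}

#' Per-locus heterozygosity
#' @param pop a `haplo_pop`.
#' @return numeric vector, fraction of heterozygous individuals per locus.
#' @export
heterozygosity <- function(pop) colMeans(pop$hap1 != pop$hap2)

#' Per-locus allele-1 frequency (over haplotypes)
#' @param pop a `haplo_pop`.
#' @return numeric vector of allele-1 frequencies.
#' @export
allele_freq <- function(pop) (colSums(pop$hap1) + colSums(pop$hap2)) / (2 * n_ind(pop))
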