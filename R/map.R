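#' Genetic map
#'
#' A genetic map places every locus on a chromosome at a position in
#' centimorgans. Positions must be strictly increasing within a chromosome
#' and locus identifiers must be globally unique.
#'
#' @param locus_id character vector of unique locus identifiers.
#' @param chromosome chromosome identifier per locus (coerced to character).
#' @param pos_cM numeric map position per locus, in centimorgans.
#'
#' @return An object of class `genetic_map`: a data frame with columns
#'   `locus_id`, `chromosome`, `pos_cM`, ordered by chromosome then position.
#' @export
genetic_map <- function(locus_id, chromosome, pos_cM) {
  locus_id <- as.character(locus_id)
  chromosome <- as.character(chromosome)
  pos_cM <- as.numeric(pos_cM)
  if (length(locus_id) != length(chromosome) || length(locus_id) != length(pos_cM))
    stop("locus_id, chromosome and pos_cM must have equal length")
  if (anyDuplicated(locus_id))
    stop("duplicated locus id: ", locus_id[duplicated(locus_id)][1L])
  if (anyNA(pos_cM)) stop("non-numeric map position")
  m <- data.frame(locus_id = locus_id, chromosome = chromosome,
                  pos_cM = pos_cM, stringsAsFactors = FALSE)
  # preserve chromosome order of first appearance, sort loci within chromosome
  chr_levels <- unique(chromosome)
  m <- m[order(match(m$chromosome, chr_levels), m$pos_cM), , drop = FALSE]
  rownames(m) <- NULL
  for (ch in chr_levels) {
    p <- m$pos_cM[m$chromosome == ch]
    if (any(diff(p) <= 0))
      stop("map positions not strictly increasing on chromosome ", ch)
  }
  structure(m, class = c("genetic_map", "data.frame"))
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", nrow(x), "loci on", length(unique(x$chromosome)),
      "chromosome(s)\n")
  invisible(x)
}

#' Number of loci on a genetic map
#' @param map a `genetic_map`.
#' @return integer locus count.
#' @export
n_loci <- function(map) nrow(map)

# split a map into per-chromosome index/position lists (internal, hot path)
map_chromosomes <- function(map) {
  chr <- unique(map$chromosome)
  lapply(chr, function(ch) {
    idx <- which(map$chromosome == ch)
    list(chromosome = ch, idx = idx, pos = map$pos_cM[idx])
  })
}

#' Evenly spaced synthetic genetic map
#'
#' Builds a map with `n_loci` loci distributed as evenly as possible over
#' `n_chromosomes` chromosomes of equal length, loci uniformly spaced.
#'
#' @param n_loci total locus count.
#' @param n_chromosomes chromosome count.
#' @param chrom_length_cM chromosome length in centimorgans (default 150).
#' @return a `genetic_map`.
#' @export
uniform_map <- function(n_loci, n_chromosomes, chrom_length_cM = 150) {
  if (n_loci < n_chromosomes) stop("n_loci must be >= n_chromosomes")
  per <- rep(n_loci %/% n_chromosomes, n_chromosomes)
  extra <- n_loci %% n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  chrom <- rep(sprintf("chr%d", seq_len(n_chromosomes)), per)
  pos <- unlist(lapply(per, function(k) seq(0, chrom_length_cM, length.out = k)))
  genetic_map(sprintf("L%04d", seq_len(n_loci)), chrom, pos)
}
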