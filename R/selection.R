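#' Couple plan
#'
#' Ordered crossing-block design: one row per couple with parent ids, the
#' selection method and the provenance of each parent (how it was chosen).
#' An individual can parent at most one couple.
#'
#' @param P1,P2 character vectors of parent ids.
#' @param method selection method tag.
#' @param p1_source,p2_source per-parent provenance tags.
#' @return A data frame of class `couple_plan` with columns `couple_index`,
#'   `P1`, `P2`, `method`, `p1_source`, `p2_source`.
#' @export
couple_plan <- function(P1, P2, method,
                        p1_source = "unspecified", p2_source = "unspecified") {
  if (length(P1) != length(P2)) stop("P1 and P2 must have equal length")
  all_par <- c(P1, P2)
  if (anyDuplicated(all_par))
    stop("individual used as parent more than once: ",
         all_par[duplicated(all_par)][1L])
  out <- data.frame(couple_index = seq_along(P1), P1 = P1, P2 = P2,
                    method = method,
                    p1_source = p1_source, p2_source = p2_source,
                    stringsAsFactors = FALSE)
  class(out) <- c("couple_plan", "data.frame")
  out
}

#' Write a couple plan as TSV
#' @param plan a `couple_plan`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_couple_plan <- function(plan, path) {
  utils::write.table(as.data.frame(plan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# order ids by decreasing score, ties by ascending id (the package-wide
# deterministic tie rule)
order_by_score <- function(score, ids) order(-score, ids)

# random pairing of an even set of selected parents into couples
random_pairs <- function(sel_ids) {
  perm <- sample(length(sel_ids))
  m <- matrix(sel_ids[perm], ncol = 2L, byrow = TRUE)
  list(P1 = m[, 1L], P2 = m[, 2L])
}

#' Truncation selection
#'
#' Selects the `n_parents` individuals with the highest GEBVs (ties broken
#' by ascending id) and pairs them uniformly at random into couples.
#'
#' @param gebvs named numeric vector of GEBVs (names = individual ids).
#' @param n_parents even number of parents to select.
#' @return a [couple_plan()].
#' @export
truncation_select <- function(gebvs, n_parents) {
  if (n_parents %% 2L != 0L) stop("n_parents must be even")
  if (length(gebvs) < n_parents) stop("population smaller than n_parents")
  ids <- names(gebvs)
  if (is.null(ids)) stop("gebvs must be named by individual id")
  sel <- ids[order_by_score(gebvs, ids)][seq_len(n_parents)]
  pr <- random_pairs(sel)
  couple_plan(pr$P1, pr$P2, "truncation", "gebv", "gebv")
}

#' F-score of a candidate parental set
#'
#' Sum over markers of the (population-denominator) variance of the dosage
#' column, masked by the Boolean vector `p` that flags markers at which one
#' of the two alleles is still missing from the selected parents. A high
#' F-score rewards candidate sets that keep both alleles represented at as
#' many markers as possible.
#'
#' @param Z dosage matrix (rows = already-selected parents plus the
#'   candidate) at the marker loci.
#' @param p 0/1 vector over markers; must not be all zero (the reset rule
#'   restores an all-zero `p` to all ones before scoring).
#' @return a single numeric score.
#' @export
f_score <- function(Z, p) {
  if (nrow(Z) < 2L) stop("F-score needs at least 2 rows")
  if (all(p == 0)) stop("p must not be all zero (apply the reset rule first)")
  v <- colMeans(Z^2) - colMeans(Z)^2
  sum(v * p)
}

# update the scoping mask after a parent joins: p_i <- 0 where both alleles
# are present among the selected parents; all-zero p resets to all-ones
update_p <- function(p, Zsel) {
  both <- (apply(Zsel, 2L, max) > -1L) & (apply(Zsel, 2L, min) < 1L)
  p[both] <- 0
  if (all(p == 0)) p[] <- 1
  p
}

# vectorized F-score of (selected + one candidate) for every candidate row
f_score_candidates <- function(Zsel, Zcand, p) {
  s <- nrow(Zsel)
  s1 <- colSums(Zsel); s2 <- colSums(Zsel^2)
  M1 <- sweep(Zcand, 2L, s1, `+`) / (s + 1)
  M2 <- sweep(Zcand^2, 2L, s2, `+`) / (s + 1)
  as.numeric((M2 - M1^2) %*% p)
}

#' Scoping selection
#'
#' Two-stage parental selection that trades a little selection intensity for
#' the retention of marker-allele diversity. Stage 1 preselects the top
#' `ceiling(SR * n)` individuals by GEBV. Stage 2 builds couples
#' sequentially: P1 is the highest-GEBV preselected individual not yet
#' chosen; P2 is the preselected candidate maximizing the [f_score()] of the
#' already-selected parents plus the candidate. After each parent joins, the
#' marker mask `p` is zeroed where both alleles are present among selected
#' parents (reset to all ones if it becomes all zero).
#'
#' @param marker_geno dosage matrix (individuals x markers), rownames = ids.
#' @param gebvs named numeric GEBV vector aligned with the population.
#' @param SR scoping rate: fraction of the population preselected.
#' @param n_parents even number of parents.
#' @return a [couple_plan()].
#' @export
scoping_select <- function(marker_geno, gebvs, SR, n_parents) {
  st <- scoping_state(marker_geno, gebvs, SR, n_parents)
  for (cpl in seq_len(n_parents %/% 2L)) st <- scoping_couple(st)
  couple_plan(st$P1, st$P2, "scoping", "gebv", "f_score")
}

# shared scoping machinery (also used by chimeric scoping)
scoping_state <- function(marker_geno, gebvs, SR, n_parents) {
  if (n_parents %% 2L != 0L) stop("n_parents must be even")
  ids <- rownames(marker_geno)
  if (is.null(ids)) stop("marker_geno must have rownames (individual ids)")
  npre <- ceiling(SR * nrow(marker_geno))
  if (npre < n_parents) stop("preselection (", npre, ") smaller than n_parents")
  pre <- ids[order_by_score(gebvs[ids], ids)][seq_len(npre)]
  list(Z = marker_geno, gebvs = gebvs, pre = pre,
       p = rep(1, ncol(marker_geno)), selected = character(0),
       P1 = character(0), P2 = character(0))
}

scoping_pick_f <- function(st, pool) {
  Zsel <- st$Z[st$selected, , drop = FALSE]
  f <- f_score_candidates(Zsel, st$Z[pool, , drop = FALSE], st$p)
  pool[order_by_score(f, pool)][1L]
}

scoping_add <- function(st, id) {
  st$selected <- c(st$selected, id)
  st$p <- update_p(st$p, st$Z[st$selected, , drop = FALSE])
  st
}

scoping_couple <- function(st) {
  avail <- setdiff(st$pre, st$selected)
  p1 <- avail[order_by_score(st$gebvs[avail], avail)][1L]
  st <- scoping_add(st, p1)
  avail <- setdiff(st$pre, st$selected)
  p2 <- scoping_pick_f(st, avail)
  st <- scoping_add(st, p2)
  st$P1 <- c(st$P1, p1); st$P2 <- c(st$P2, p2)
  st
}

f_only_couple <- function(st, pool_ids) {
  avail <- setdiff(pool_ids, st$selected)
  if (length(st$selected) == 0L) {
    # the F-score needs >= 2 rows; seed the set with the candidate carrying
    # the most minority alleles (ties by id), which an F-score maximizer
    # would favor next anyway
    fr <- colMeans(st$Z[pool_ids, , drop = FALSE])
    score <- rowSums(abs(sweep(st$Z[avail, , drop = FALSE], 2L, sign(fr))))
    p1 <- avail[order_by_score(score, avail)][1L]
  } else {
    p1 <- scoping_pick_f(st, avail)
  }
  st <- scoping_add(st, p1)
  avail <- setdiff(pool_ids, st$selected)
  p2 <- scoping_pick_f(st, avail)
  st <- scoping_add(st, p2)
  st$P1 <- c(st$P1, p1); st$P2 <- c(st$P2, p2)
  st
}

#' Chimeric scoping selection
#'
#' Splits the crossing block in two: the first `N` couples follow the
#' scoping mechanics (P1 by GEBV from the preselected pool, P2 by F-score);
#' the remaining couples choose both parents purely as F-score maximizers
#' from the whole population, fully prioritizing genetic variation. The
#' marker mask `p` and the selected-parent set are shared across the whole
#' plan.
#'
#' @inheritParams scoping_select
#' @param N number of leading couples built with scoping mechanics
#'   (`0 <= N <= n_parents / 2`).
#' @return a [couple_plan()].
#' @export
chimeric_scoping_select <- function(marker_geno, gebvs, N, SR, n_parents) {
  n_couples <- n_parents %/% 2L
  if (N < 0L || N > n_couples) stop("N must be between 0 and n_parents / 2")
  st <- scoping_state(marker_geno, gebvs, SR, n_parents)
  for (cpl in seq_len(N)) st <- scoping_couple(st)
  all_ids <- rownames(marker_geno)
  for (cpl in seq_len(n_couples - N)) st <- f_only_couple(st, all_ids)
  src1 <- c(rep("gebv", N), rep("f_score", n_couples - N))
  src2 <- rep("f_score", n_couples)
  couple_plan(st$P1, st$P2, "chimeric_scoping", src1, src2)
}

#' Oracle parental selection
#'
#' Ground-truth selection that greedily secures favorable QTL alleles.
#' Each unselected individual is scored by the number of QTLs at which it
#' carries at least one favorable allele, restricted to QTLs whose
#' favorable allele is absent from every already-selected parent (and still
#' present somewhere in the population: alleles the population has lost can
#' never be secured and are excluded from the priority); when no such QTL
#' remains, the score is computed over all QTLs. The arg-max
#' (ties by ascending id) joins the parental set; the process repeats until
#' `n_parents` parents are chosen, after which they are paired uniformly at
#' random.
#'
#' @param population a `haplo_pop`.
#' @param qtl_model a `qtl_model` (oracle privilege: true QTL positions and
#'   favorable alleles).
#' @param n_parents even number of parents.
#' @return a [couple_plan()].
#' @export
oracle_parent_select <- function(population, qtl_model, n_parents) {
  if (n_parents %% 2L != 0L) stop("n_parents must be even")
  if (n_ind(population) < n_parents) stop("population smaller than n_parents")
  ids <- population$ids
  fav <- qtl_model$favorable
  q <- qtl_model$qtl_idx
  # carries >= 1 favorable allele at each QTL (het or favorable homozygote)
  B <- (sweep(population$hap1[, q, drop = FALSE], 2L, fav, `==`) |
        sweep(population$hap2[, q, drop = FALSE], 2L, fav, `==`))
  storage.mode(B) <- "integer"
  # a favorable allele absent from the whole population can never be secured;
  # such QTLs are excluded from the coverage priority outright
  securable <- colSums(B) > 0L
  selected <- character(0)
  covered <- rep(FALSE, qtl_model$L)
  for (s in seq_len(n_parents)) {
    avail <- setdiff(ids, selected)
    open <- which(!covered & securable)
    score <- if (length(open)) rowSums(B[match(avail, ids), open, drop = FALSE])
             else rowSums(B[match(avail, ids), , drop = FALSE])
    pick <- avail[order_by_score(score, avail)][1L]
    selected <- c(selected, pick)
    covered <- covered | (B[match(pick, ids), ] == 1L)
  }
  pr <- random_pairs(selected)
  couple_plan(pr$P1, pr$P2, "oracle", "oracle_priority", "oracle_priority")
}
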