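# Fixtures and independent brute-force oracles used across the test files.
# Everything here is built in code; the brute-force routines deliberately use
# naive dense linear algebra and literal loops, independent of the package's
# optimized code paths.

# tiny fully-inbred population from a dosage matrix in {-1, 1} (or {-1,0,1}
# with explicit het rows when allow_het = TRUE)
pop_from_dosage <- function(dos, map = NULL, ids = NULL) {
  dos <- as.matrix(dos)
  if (is.null(map)) map <- uniform_map(ncol(dos), 1, chrom_length_cM = 100)
  if (is.null(ids))
    ids <- if (!is.null(rownames(dos))) rownames(dos)
           else sprintf("I%02d", seq_len(nrow(dos)))
  hap1 <- (dos >= 0) * 1L
  hap2 <- (dos > 0) * 1L
  haplo_pop(hap1, hap2, map, ids)
}

# QTL model with fully specified internals (bypasses random construction)
manual_qtl_model <- function(qtl_idx, favorable, n_total_loci) {
  L <- length(qtl_idx)
  a <- (L - 1) / (L + 1)
  effects <- a^seq_len(L)
  structure(list(qtl_idx = qtl_idx, favorable = favorable, effects = effects,
                 marker_idx = setdiff(seq_len(n_total_loci), qtl_idx),
                 a = a, L = L, denom = sum(effects)),
            class = "qtl_model")
}

# small founder set built in code
toy_founders <- function(n_per_group = c(30, 30), n_loci = 60, seed = 42,
                         ld_decay = 0.8) {
  generate_synthetic_founders(n_per_group, n_loci = n_loci, n_chromosomes = 3,
                              ld_decay = ld_decay, seed = seed)
}

# ---- independent REML oracle: dense profiled restricted likelihood --------
# -2 REML loglik (up to an additive constant) at fixed lambda via determinant
# and solve() on the full n x n system; no eigendecomposition.
brute_reml_neg2ll <- function(log_lambda, Z, y) {
  lam <- exp(log_lambda)
  n <- length(y)
  H <- Z %*% t(Z) + lam * diag(n)
  Hi <- solve(H)
  one <- rep(1, n)
  s11 <- drop(t(one) %*% Hi %*% one)
  P <- Hi - (Hi %*% one %*% t(one) %*% Hi) / s11
  ypy <- drop(t(y) %*% P %*% y)
  determinant(H, logarithm = TRUE)$modulus + log(s11) + (n - 1) * log(ypy)
}

# ---- independent PEV/CD oracle: explicit dense MME inversion ---------------
# coefficient matrix [[1'1, 1'Z], [Z'1, Z'Z + lambda I]]; PEV of contrast c
# on u is sigma_e2 * [0, c]' Cinv [0, c].
brute_pev <- function(Z, lambda, sigma_e2, contrasts) {
  n <- nrow(Z); k <- ncol(Z)
  one <- rep(1, n)
  C <- rbind(cbind(sum(one), t(one) %*% Z),
             cbind(t(Z) %*% one, t(Z) %*% Z + lambda * diag(k)))
  Cinv <- solve(C)
  apply(contrasts, 1L, function(cc) {
    v <- c(0, cc)
    sigma_e2 * drop(t(v) %*% Cinv %*% v)
  })
}

# population-denominator column variance, written naively
pop_var <- function(x) mean(x^2) - mean(x)^2

# ---- brute-force scoping P2 choice ----------------------------------------
# given dosage rows of already-selected parents, a candidate pool and the
# marker mask p, return the id of the candidate maximizing the F-score of
# selected + candidate (ties by ascending id)
brute_scoping_p2 <- function(Z, selected_ids, pool_ids, p) {
  f <- sapply(pool_ids, function(id) {
    rows <- Z[c(selected_ids, id), , drop = FALSE]
    sum(apply(rows, 2L, pop_var) * p)
  })
  pool_ids[order(-f, pool_ids)][1L]
}

# ---- brute-force oracle parental selection (literal greedy replay) ---------
brute_oracle_parents <- function(pop, qtl, n_parents) {
  ids <- pop$ids
  L <- qtl$L
  carries <- function(ind, l) {
    loc <- qtl$qtl_idx[l]
    pop$hap1[ind, loc] == qtl$favorable[l] || pop$hap2[ind, loc] == qtl$favorable[l]
  }
  securable <- vapply(seq_len(L), function(l)
    any(vapply(seq_along(ids), carries, logical(1), l = l)), logical(1))
  selected <- character(0)
  for (s in seq_len(n_parents)) {
    open <- Filter(function(l) {
      securable[l] &&
        !any(vapply(match(selected, ids), carries, logical(1), l = l))
    }, seq_len(L))
    use <- if (length(open)) open else seq_len(L)
    avail <- setdiff(ids, selected)
    score <- vapply(avail, function(id)
      sum(vapply(use, function(l) carries(match(id, ids), l), logical(1))),
      numeric(1))
    selected <- c(selected, avail[order(-score, avail)][1L])
  }
  selected
}

# ---- naive mixed-model solve at fixed lambda (dense, base solve()) ---------
naive_gebv <- function(Ztp, ytp, lambda, Znew) {
  n <- nrow(Ztp)
  H <- Ztp %*% t(Ztp) + lambda * diag(n)
  Hi <- solve(H)
  one <- rep(1, n)
  beta <- drop(t(one) %*% Hi %*% ytp) / drop(t(one) %*% Hi %*% one)
  u <- t(Ztp) %*% Hi %*% (ytp - beta * one)
  drop(Znew %*% u)
}
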