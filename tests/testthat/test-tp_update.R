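make_tp <- function(n, k, seed = 1, entry = NULL) {
  set.seed(seed)
  Z <- matrix(sample(c(-1, 0, 1), n * k, replace = TRUE), n, k)
  u <- rnorm(k)
  y <- as.numeric(Z %*% u) + rnorm(n)
  training_set(Z, y, if (is.null(entry)) rep(0L, n) else entry,
               sprintf("tp%03d", seq_len(n)))
}

make_pop <- function(n, k, seed = 2, prefix = "p") {
  set.seed(seed)
  Z <- matrix(sample(c(-1, 0, 1), n * k, replace = TRUE), n, k,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n)), NULL))
  Z
}

test_that("the tails update adds equal numbers from both GEBV extremes", {
  k <- 8
  tp <- make_tp(20, k)
  pheno <- build_phenotype_model(rnorm(100), h2 = 0.5)
  pop <- make_pop(300, k)
  gebvs <- setNames(seq_len(300), rownames(pop))
  g_true <- setNames(rnorm(300), rownames(pop))
  up <- standard_update(tp, pop, gebvs, g_true, pheno, "tails",
                        n_add = 150, n_drop_oldest = 0, cycle = 2)
  added <- up$report$added
  expect_length(added, 150L)
  ranks <- gebvs[added]
  expect_equal(sum(ranks > 150), 75L)     # 75 highest
  expect_equal(sum(ranks <= 150), 75L)    # 75 lowest
  expect_setequal(added, c(rownames(pop)[151:225 + 75], rownames(pop)[1:75]))
  expect_error(standard_update(tp, pop, gebvs, g_true, pheno, "tails",
                               n_add = 7, n_drop_oldest = 0, cycle = 2),
               "even")
})

test_that("oldest members leave first and bookkeeping balances", {
  k <- 6
  tp <- make_tp(12, k, entry = rep(c(0L, 1L, 2L), each = 4))
  pheno <- build_phenotype_model(rnorm(50), h2 = 0.5)
  pop <- make_pop(40, k)
  gebvs <- setNames(rnorm(40), rownames(pop))
  g_true <- setNames(rnorm(40), rownames(pop))
  set.seed(9)
  up <- standard_update(tp, pop, gebvs, g_true, pheno, "top",
                        n_add = 5, n_drop_oldest = 4, cycle = 3)
  expect_setequal(up$report$removed, tp$ids[tp$entry_cycle == 0L])
  expect_equal(up$report$tp_size_after, 12 - 4 + 5)
  expect_equal(nrow(up$tp$Z), 13L)
  expect_true(all(up$tp$entry_cycle[up$tp$ids %in% up$report$added] == 3L))
  # top additions are the highest GEBVs
  expect_setequal(up$report$added,
                  names(sort(gebvs, decreasing = TRUE))[1:5])

  # no-op update leaves the TP identical
  up0 <- standard_update(tp, pop, gebvs, g_true, pheno, "top",
                         n_add = 0, n_drop_oldest = 0, cycle = 3)
  expect_identical(up0$tp$Z, tp$Z)
  expect_identical(up0$tp$ids, tp$ids)

  # random additions are seed-reproducible
  set.seed(11)
  a <- standard_update(tp, pop, gebvs, g_true, pheno, "random", 6, 0, 3)
  set.seed(11)
  b <- standard_update(tp, pop, gebvs, g_true, pheno, "random", 6, 0, 3)
  expect_identical(a$report$added, b$report$added)
})

test_that("criterion updates equal exhaustive one-step search", {
  k <- 6
  tp <- make_tp(10, k, seed = 21)
  fit <- fit_rrblup(tp)
  pop <- make_pop(8, k, seed = 22)
  g_true <- setNames(rnorm(8), rownames(pop))
  pheno <- build_phenotype_model(rnorm(50), h2 = 0.5)

  for (method in c("pevmean", "cdmean")) {
    set.seed(23)
    up <- criterion_update(tp, pop, g_true, pheno, fit, method,
                           n_add = 1, n_drop_oldest = 0, cycle = 1)
    # exhaustive: score every candidate by the resulting mean criterion
    vals <- sapply(rownames(pop), function(cand) {
      Zt <- rbind(tp$Z, pop[cand, , drop = FALSE])
      targets <- setdiff(rownames(pop), cand)
      pev <- brute_pev(Zt, fit$lambda, fit$sigma_e2,
                       sweep(pop[targets, , drop = FALSE], 2, colMeans(Zt)))
      if (method == "pevmean") mean(pev)
      else {
        ctc <- rowSums(sweep(pop[targets, , drop = FALSE], 2, colMeans(Zt))^2)
        mean(1 - pev / (fit$sigma_u2 * ctc))
      }
    })
    best <- if (method == "pevmean") names(which.min(vals)) else names(which.max(vals))
    expect_identical(up$report$added, best)
  }

  # empty candidate pool: unchanged
  up0 <- criterion_update(tp, pop[0, , drop = FALSE], g_true, pheno, fit,
                          "pevmean", n_add = 3, n_drop_oldest = 0, cycle = 1)
  expect_identical(up0$tp$ids, tp$ids)
})

test_that("criterion updates prefer candidates that enlarge the genotype row space", {
  k <- 5
  set.seed(31)
  Z <- matrix(sample(c(-1, 1), 8 * k, replace = TRUE), 8, k)
  tp <- training_set(Z, as.numeric(Z %*% rnorm(k)) + rnorm(8), rep(0L, 8),
                     sprintf("t%d", 1:8))
  fit <- fit_rrblup(tp, lambda = 1)
  dup <- tp$Z[1, , drop = FALSE]          # duplicates an existing member
  fresh <- matrix(c(-1, 0, 1, 0, -1), 1)  # new direction
  pop <- rbind(dup, fresh)
  rownames(pop) <- c("a_dup", "b_new")
  g_true <- setNames(rnorm(2), rownames(pop))
  pheno <- build_phenotype_model(rnorm(50), h2 = 0.5)
  set.seed(32)
  up <- criterion_update(tp, pop, g_true, pheno, fit, "pevmean",
                         n_add = 1, n_drop_oldest = 0, cycle = 1)
  expect_identical(up$report$added, "b_new")
})

test_that("the oracle TP update is a no-op at zero caps and respects add/remove exclusivity", {
  k <- 8
  tp <- make_tp(10, k, seed = 41)
  pop <- make_pop(20, k, seed = 42)
  g_true <- setNames(as.numeric(pop %*% rnorm(k)), rownames(pop))
  pheno <- build_phenotype_model(g_true, h2 = 0.5)
  set.seed(43)
  up0 <- oracle_tp_update(tp, pop, g_true, pheno, cycle = 1,
                          max_add = 0, max_remove = 0)
  expect_identical(up0$tp$ids, tp$ids)
  expect_length(up0$report$added, 0L)

  set.seed(44)
  up <- oracle_tp_update(tp, pop, g_true, pheno, cycle = 1,
                         max_add = 5, max_remove = 5)
  expect_length(intersect(up$report$added, up$report$removed), 0L)
  expect_equal(up$report$tp_size_after,
               nrow(tp$Z) + length(up$report$added) - length(up$report$removed))
})

test_that("the first oracle addition equals exhaustive one-step search", {
  k <- 6
  tp <- make_tp(8, k, seed = 51)
  pop <- make_pop(12, k, seed = 52)
  set.seed(53)
  g_true <- setNames(as.numeric(pop %*% rnorm(k)), rownames(pop))
  pheno <- build_phenotype_model(g_true, h2 = 0.9)
  set.seed(54)
  up <- oracle_tp_update(tp, pop, g_true, pheno, cycle = 1,
                         max_add = 1, max_remove = 0)
  expect_length(up$report$added, 1L)

  # exhaustive replay with an independent dense solver: reconstruct the
  # phenotyping batch (first RNG draw after the seed), then score every
  # candidate at the loop-start lambda
  set.seed(54)
  y_pop <- simulate_phenotypes(g_true[rownames(pop)], pheno)
  lam <- fit_rrblup(tp)$lambda
  ev <- rownames(pop)
  r <- sapply(rownames(pop), function(cand) {
    Zt <- rbind(tp$Z, pop[cand, , drop = FALSE])
    cor(naive_gebv(Zt, c(tp$y, y_pop[[cand]]), lam, pop[ev, ]), g_true[ev])
  })
  best <- names(r)[order(-r, names(r))][1]
  expect_identical(up$report$added, best)
  expect_gt(r[[best]], cor(naive_gebv(tp$Z, tp$y, lam, pop[ev, ]), g_true[ev]))
})

test_that("the greedy oracle trace improves performance monotonically under low noise", {
  k <- 10
  pop <- make_pop(30, k, seed = 61)
  set.seed(62)
  g_true <- setNames(as.numeric(pop %*% rnorm(k)), rownames(pop))
  pheno <- build_phenotype_model(g_true, h2 = 0.999)
  pheno$sigmaE2 <- 0; pheno$sigmaR2 <- 0    # noiseless oracle scenario
  # adversarial seed TP: constant-ish genotypes, noisy y
  set.seed(63)
  Zt <- matrix(sample(c(-1, 0, 1), 5 * k, replace = TRUE), 5, k)
  tp <- training_set(Zt, as.numeric(Zt %*% rnorm(k)) + rnorm(5, 0, 3),
                     rep(0L, 5), sprintf("bad%d", 1:5))
  set.seed(64)
  up <- oracle_tp_update(tp, pop, g_true, pheno, cycle = 1,
                         max_add = 15, max_remove = 15, refit_every = 5)
  lam <- fit_rrblup(tp)$lambda
  ev0 <- rownames(pop)
  init_perf <- cor(naive_gebv(tp$Z, tp$y, lam, pop[ev0, ]), g_true[ev0])
  final_ev <- setdiff(rownames(pop), up$report$added)
  Zf <- up$tp$Z; yf <- up$tp$y
  final_perf <- cor(naive_gebv(Zf, yf, up$model$lambda, pop[final_ev, ]),
                    g_true[final_ev])
  expect_gt(final_perf, init_perf)
  tr <- up$report$trace
  expect_false(is.null(tr))
  # every accepted step strictly improved the performance it was judged on
  expect_true(all(tr$perf_eval > tr$perf_before))
})

test_that("vectorized oracle addition scoring matches naive dense refits", {
  k <- 7
  tp <- make_tp(9, k, seed = 71)
  pop <- make_pop(10, k, seed = 72)
  set.seed(73)
  g_true <- setNames(as.numeric(pop %*% rnorm(k)) + rnorm(10, 0, 0.5),
                     rownames(pop))
  pheno <- build_phenotype_model(g_true, h2 = 0.5)
  lam <- 3.7
  set.seed(74)
  y_pop <- simulate_phenotypes(g_true[rownames(pop)], pheno)
  ev <- rownames(pop)
  # package route: internal formulas reproduced through oracle_tp_update's
  # building blocks -- here validated against naive refit for every candidate
  for (cand in rownames(pop)) {
    Zt2 <- rbind(tp$Z, pop[cand, , drop = FALSE])
    yt2 <- c(tp$y, y_pop[[cand]])
    ref <- naive_gebv(Zt2, yt2, lam, pop[ev, ])
    pkg <- gsoracle:::kernel_predict(Zt2, yt2, lam, pop[ev, ])
    expect_equal(pkg, ref, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("block-inverse add and downdate remove evaluations match dense refits", {
  # replay every accepted greedy step with an independent dense solver and
  # check the recorded evaluation values to numerical precision
  k <- 9
  tp <- make_tp(10, k, seed = 81)
  pop <- make_pop(16, k, seed = 82)
  set.seed(83)
  g_true <- setNames(as.numeric(pop %*% rnorm(k)) + rnorm(16, 0, 0.3),
                     rownames(pop))
  pheno <- build_phenotype_model(g_true, h2 = 0.7)
  set.seed(84)
  up <- oracle_tp_update(tp, pop, g_true, pheno, cycle = 2,
                         max_add = 6, max_remove = 6, refit_every = 999L)
  tr <- up$report$trace
  expect_gt(nrow(tr), 0)

  set.seed(84)
  y_pop <- simulate_phenotypes(g_true[rownames(pop)], pheno)
  lam <- fit_rrblup(tp)$lambda
  Zt <- tp$Z; yt <- tp$y; idt <- tp$ids
  accepted <- character(0)
  for (s in seq_len(nrow(tr))) {
    ev <- setdiff(rownames(pop), accepted)
    if (tr$action[s] == "add") {
      Z2 <- rbind(Zt, pop[tr$id[s], , drop = FALSE])
      y2 <- c(yt, y_pop[[tr$id[s]]])
      accepted <- c(accepted, tr$id[s])
    } else {
      i <- match(tr$id[s], idt)
      Z2 <- Zt[-i, , drop = FALSE]; y2 <- yt[-i]
    }
    ref <- cor(naive_gebv(Z2, y2, lam, pop[ev, ]), g_true[ev])
    expect_equal(tr$perf_eval[s], ref, tolerance = 1e-8)
    Zt <- Z2; yt <- y2
    idt <- if (tr$action[s] == "add") c(idt, tr$id[s]) else idt[-i]
  }
})

test_that("a TP snapshot writes one row per member", {
  tp <- make_tp(6, 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tp_snapshot(tp, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 6L)
  expect_equal(back$id, tp$ids)
  expect_equal(back$phenotype, tp$y)
})
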