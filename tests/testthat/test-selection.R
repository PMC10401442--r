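test_that("truncation selection takes the top GEBVs with stable tie-breaking", {
  gebvs <- setNames(as.numeric(1:200), sprintf("i%03d", 1:200))
  set.seed(1)
  plan <- truncation_select(gebvs, 100)
  sel <- sort(c(plan$P1, plan$P2))
  expect_identical(sel, sort(sprintf("i%03d", 101:200)))
  expect_equal(nrow(plan), 50L)

  # all GEBVs equal: first n in ascending id order
  flat <- setNames(rep(0, 10), sprintf("x%02d", 10:1))
  set.seed(2)
  plan2 <- truncation_select(flat, 4)
  expect_identical(sort(c(plan2$P1, plan2$P2)), sprintf("x%02d", 1:4))

  # pairing is driven by the RNG stream: fixed seed, fixed couples
  set.seed(5); a <- truncation_select(gebvs, 100)
  set.seed(5); b <- truncation_select(gebvs, 100)
  expect_identical(a, b)
  expect_error(truncation_select(gebvs, 99), "even")
})

test_that("the F-score is the p-masked sum of population column variances", {
  Z <- rbind(c(1, 1), c(1, 1))
  expect_equal(f_score(Z, c(1, 1)), 0)
  Z2 <- rbind(c(1, 1), c(-1, -1))
  expect_equal(f_score(Z2, c(1, 1)), 2)   # population variance of {+1,-1} is 1
  expect_equal(f_score(Z2, c(1, 0)), 1)
  expect_error(f_score(Z2, c(0, 0)), "all zero")
  expect_error(f_score(Z2[1, , drop = FALSE], c(1, 1)), "2 rows")
})

test_that("scoping preselects ceiling(SR * n) individuals and picks complementary mates", {
  # preselection size
  Z <- matrix(sample(c(-1L, 1L), 1000 * 5, replace = TRUE), 1000, 5,
              dimnames = list(sprintf("i%04d", 1:1000), NULL))
  gebvs <- setNames(rnorm(1000), rownames(Z))
  st <- gsoracle:::scoping_state(Z, gebvs, SR = 0.3, n_parents = 100)
  expect_length(st$pre, 300L)

  # 4-individual toy: two identical elites plus one complementary line.
  # P1 = top GEBV elite; P2 must be the complementary line, as found by
  # exhaustive search over all candidates.
  Zt <- rbind(e1 = c(1, 1, 1), e2 = c(1, 1, 1), comp = c(-1, -1, -1),
              near = c(1, 1, -1))
  g <- setNames(c(4, 3, 1, 2), rownames(Zt))
  plan <- scoping_select(Zt, g, SR = 1, n_parents = 2)
  expect_identical(plan$P1, "e1")
  brute <- brute_scoping_p2(Zt, "e1", c("e2", "comp", "near"), rep(1, 3))
  expect_identical(plan$P2, brute)
  expect_identical(plan$P2, "comp")

  # identical candidates: selection follows GEBV order, F ties broken by id
  Zs <- matrix(1L, 6, 3, dimnames = list(sprintf("s%d", 1:6), NULL))
  gs <- setNames(c(6, 5, 4, 3, 2, 1), rownames(Zs))
  plan2 <- scoping_select(Zs, gs, SR = 1, n_parents = 4)
  expect_identical(plan2$P1, c("s1", "s3"))
  expect_identical(plan2$P2, c("s2", "s4"))
  expect_error(scoping_select(Zs, gs, SR = 0.3, n_parents = 4), "preselection")
})

test_that("scoping P2 choices replicate exhaustive search on random instances", {
  set.seed(44)
  for (rep in 1:15) {
    n <- sample(6:10, 1); k <- sample(3:8, 1)
    Z <- matrix(sample(c(-1L, 0L, 1L), n * k, replace = TRUE), n, k,
                dimnames = list(sprintf("r%02d", 1:n), NULL))
    g <- setNames(rnorm(n), rownames(Z))
    plan <- scoping_select(Z, g, SR = 1, n_parents = 4)
    # replay: P1 by GEBV; p updated; P2 by brute force
    ids <- rownames(Z)
    p1 <- ids[order(-g, ids)][1]
    p <- gsoracle:::update_p(rep(1, k), Z[p1, , drop = FALSE])
    p2 <- brute_scoping_p2(Z, p1, setdiff(ids, p1), p)
    expect_identical(plan$P1[1], p1)
    expect_identical(plan$P2[1], p2)
  }
})

test_that("the p mask zeroes covered markers and resets when exhausted", {
  Zsel <- rbind(c(1, 1, 0), c(-1, 1, 1))
  # marker 1: both alleles; marker 2: only allele 1; marker 3: het = both
  expect_equal(gsoracle:::update_p(c(1, 1, 1), Zsel), c(0, 1, 0))
  # covering everything resets to all ones
  Zall <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(gsoracle:::update_p(c(1, 1, 1), Zall), c(1, 1, 1))
})

test_that("oracle parental selection replays the greedy favorable-allele rule", {
  # 5-individual, 4-QTL toy: 'weak' uniquely carries favorable allele 4 and
  # must be selected second despite its low total score
  dos <- rbind(strong = c(1, 1, 1, -1),
               mid1  = c(1, 1, -1, -1),
               mid2  = c(1, -1, 1, -1),
               weak  = c(-1, -1, -1, 1),
               dull  = c(-1, -1, -1, -1))
  pop <- pop_from_dosage(dos, uniform_map(4, 1))
  qm <- manual_qtl_model(1:4, favorable = c(1L, 1L, 1L, 1L), n_total_loci = 4)
  set.seed(3)
  plan <- oracle_parent_select(pop, qm, 2)
  expect_setequal(c(plan$P1, plan$P2), c("strong", "weak"))
  expect_identical(brute_oracle_parents(pop, qm, 2)[2], "weak")

  # population fixed favorable everywhere: all scores equal L, id order
  popf <- pop_from_dosage(matrix(1, 4, 4,
                                 dimnames = list(c("d", "c", "b", "a"), NULL)),
                          uniform_map(4, 1), ids = c("d", "c", "b", "a"))
  set.seed(4)
  planf <- oracle_parent_select(popf, qm, 2)
  expect_setequal(c(planf$P1, planf$P2), c("a", "b"))
})

test_that("oracle parental sequences equal a literal brute-force replay", {
  set.seed(55)
  for (rep in 1:15) {
    n <- sample(4:8, 1); L <- sample(2:6, 1)
    dos <- matrix(sample(c(-1L, 0L, 1L), n * L, replace = TRUE), n, L)
    pop <- pop_from_dosage(dos, uniform_map(L, 1))
    qm <- manual_qtl_model(seq_len(L), sample(0:1, L, replace = TRUE), L)
    n_par <- 2 * sample(1:(n %/% 2), 1)
    plan <- oracle_parent_select(pop, qm, n_par)
    expect_setequal(c(plan$P1, plan$P2), brute_oracle_parents(pop, qm, n_par))
  }
})

test_that("first oracle parent maximizes the total favorable-allele count", {
  set.seed(66)
  dos <- matrix(sample(c(-1L, 0L, 1L), 8 * 5, replace = TRUE), 8, 5)
  pop <- pop_from_dosage(dos, uniform_map(5, 1))
  qm <- manual_qtl_model(1:5, sample(0:1, 5, replace = TRUE), 5)
  plan <- oracle_parent_select(pop, qm, 2)
  first <- brute_oracle_parents(pop, qm, 1)
  # the brute-force first pick appears in the plan's parents
  expect_true(first %in% c(plan$P1, plan$P2))
})

test_that("chimeric scoping shares state across its two selection regimes", {
  set.seed(77)
  n <- 12; k <- 6
  Z <- matrix(sample(c(-1L, 0L, 1L), n * k, replace = TRUE), n, k,
              dimnames = list(sprintf("c%02d", 1:n), NULL))
  g <- setNames(rnorm(n), rownames(Z))

  # N = n_couples: identical to plain scoping
  plan_full <- chimeric_scoping_select(Z, g, N = 3, SR = 1, n_parents = 6)
  plan_scope <- scoping_select(Z, g, SR = 1, n_parents = 6)
  expect_identical(plan_full$P1, plan_scope$P1)
  expect_identical(plan_full$P2, plan_scope$P2)

  # N = 0: every parent chosen by F-score, none by GEBV
  plan0 <- chimeric_scoping_select(Z, g, N = 0, SR = 1, n_parents = 6)
  expect_true(all(plan0$p1_source == "f_score"))
  expect_true(all(plan0$p2_source == "f_score"))

  # N = 1: couple 2's P2 matches brute-force F maximization given the
  # selected set after three parents
  plan1 <- chimeric_scoping_select(Z, g, N = 1, SR = 1, n_parents = 4)
  sel3 <- c(plan1$P1[1], plan1$P2[1], plan1$P1[2])
  p <- rep(1, k)
  for (s in seq_along(sel3))
    p <- gsoracle:::update_p(p, Z[sel3[seq_len(s)], , drop = FALSE])
  brute <- brute_scoping_p2(Z, sel3, setdiff(rownames(Z), sel3), p)
  expect_identical(plan1$P2[2], brute)
})

test_that("no individual parents more than one couple", {
  expect_error(couple_plan(c("a", "b"), c("c", "a"), "m"), "more than once")
  set.seed(88)
  f <- toy_founders(c(15, 15), n_loci = 30)
  qm <- build_qtl_model(f, 5)
  plan <- oracle_parent_select(f$haplotypes, qm, 10)
  expect_equal(anyDuplicated(c(plan$P1, plan$P2)), 0L)
})
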