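#' Experiment configuration
#'
#' Collects every parameter of a recurrent breeding simulation. Defaults
#' follow the reference protocol: 100 parents paired into 50 couples, 20
#' offspring per couple (1000 F1), two generations of single-seed descent,
#' heritability 0.5 over three environments, 100 QTLs, tails TP update
#' adding 150 and dropping the 150 oldest each cycle.
#'
#' @param founders either a `founder_set`, a list of synthetic-generator
#'   arguments passed to [generate_synthetic_founders()], or a list with
#'   `genotype_path`/`map_path`/`phenotype_path` for [read_founders()].
#' @param L number of QTLs.
#' @param n_couples couples per crossing block; `n_parents = 2 * n_couples`.
#' @param offspring_per_couple offspring per couple.
#' @param ssd_generations generations of single-seed descent.
#' @param n_cycles breeding cycles to simulate.
#' @param n_runs independent replicate runs.
#' @param h2 heritability of simulated phenotypes.
#' @param n_env environments per phenotyping batch.
#' @param selection list: `method` one of `"truncation"`, `"scoping"`,
#'   `"oracle"`, `"chimeric"`; `SR` scoping rate; `chimeric_ramp` a list of
#'   `c(cycle, N)` breakpoints giving the number of scoping couples from
#'   each cycle onward.
#' @param tp list: `protocol` one of `"standard"`, `"criterion"`,
#'   `"oracle"`, `"none"`; `method` (`"top"`, `"tails"`, `"random"`,
#'   `"pevmean"`, `"cdmean"`); `n_add`; `n_drop_oldest`; `initial`
#'   (`"full"` base population or `"random"`); `initial_size` (for
#'   `"random"`); `max_add`/`max_remove`/`refit_every` (oracle protocol).
#' @param var_g_reference population whose genetic variance freezes the
#'   phenotype model: `"f3"` (the cycle-1 breeding population, default) or
#'   `"founders"`.
#' @param seed master seed.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(founders = list(),
                              L = 100L,
                              n_couples = 50L,
                              offspring_per_couple = 20L,
                              ssd_generations = 2L,
                              n_cycles = 15L,
                              n_runs = 1L,
                              h2 = 0.5,
                              n_env = 3L,
                              selection = list(method = "truncation", SR = 0.3),
                              tp = list(protocol = "standard", method = "tails",
                                        n_add = 150L, n_drop_oldest = 150L,
                                        initial = "full"),
                              var_g_reference = c("f3", "founders"),
                              seed = 1L) {
  var_g_reference <- match.arg(var_g_reference)
  stopifnot(n_couples >= 1L, offspring_per_couple >= 1L, ssd_generations >= 0L,
            n_cycles >= 1L, n_runs >= 1L, L >= 1L, h2 > 0, h2 <= 1)
  sel_defaults <- list(method = "truncation", SR = 0.3, chimeric_ramp = list(c(1L, 0L)))
  tp_defaults <- list(protocol = "standard", method = "tails", n_add = 150L,
                      n_drop_oldest = 150L, initial = "full", initial_size = 100L,
                      max_add = 50L, max_remove = 50L, refit_every = 10L)
  selection <- utils::modifyList(sel_defaults, selection)
  tp <- utils::modifyList(tp_defaults, tp)
  if (!selection$method %in% c("truncation", "scoping", "oracle", "chimeric"))
    stop("unknown selection method: ", selection$method)
  if (!tp$protocol %in% c("standard", "criterion", "oracle", "none"))
    stop("unknown tp protocol: ", tp$protocol)
  structure(list(founders = founders, L = as.integer(L),
                 n_parents = 2L * as.integer(n_couples),
                 n_couples = as.integer(n_couples),
                 offspring_per_couple = as.integer(offspring_per_couple),
                 ssd_generations = as.integer(ssd_generations),
                 n_cycles = as.integer(n_cycles), n_runs = as.integer(n_runs),
                 h2 = h2, n_env = as.integer(n_env),
                 selection = selection, tp = tp,
                 var_g_reference = var_g_reference, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Keys mirror the arguments of [experiment_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(experiment_config)), "var_g_reference")
  allowed <- c(allowed, "var_g_reference")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(experiment_config, cfg)
}

#' Initial crossing block from founder phenotypes
#'
#' Ranks each subpopulation by phenotype and pairs the rank-i individual of
#' group A with the rank-i individual of group B, for `n_couples` couples
#' (phenotype ties broken by id).
#'
#' @param founders a `founder_set` with exactly two groups.
#' @param n_couples number of couples.
#' @return a [couple_plan()].
#' @export
initial_cross <- function(founders, n_couples = 50L) {
  groups <- sort(unique(founders$group))
  if (length(groups) != 2L) stop("initial cross needs exactly two founder groups")
  ids <- founders$haplotypes$ids
  pick <- lapply(groups, function(g) {
    in_g <- founders$group == g
    if (sum(in_g) < n_couples)
      stop("group ", g, " has fewer than ", n_couples, " individuals")
    gi <- ids[in_g]
    gi[order_by_score(founders$phenotypes[in_g], gi)][seq_len(n_couples)]
  })
  couple_plan(pick[[1L]], pick[[2L]], "initial_phenotype",
              "phenotype_rank", "phenotype_rank")
}

#' Mean genomic relationship between two sets of individuals
#'
#' VanRaden-style relationship: each marker column of `M` is the dosage
#' centered by twice the (base-population) alternative-allele frequency
#' minus one, and `G = M M' / (2 sum P_i (1 - P_i))`. Returns the mean of
#' the cross block of `G` between the two sets (all pairs, including
#' coinciding individuals when the sets overlap).
#'
#' @param Z1,Z2 dosage matrices (individuals x markers) on the same loci.
#' @param base_freq alternative-allele frequencies of the base population.
#' @return a single numeric value.
#' @export
genetic_relationship <- function(Z1, Z2, base_freq) {
  denom <- 2 * sum(base_freq * (1 - base_freq))
  if (denom <= 0)
    stop("all base-population allele frequencies are 0 or 1: relationship undefined")
  ctr <- 2 * (base_freq - 0.5)
  M1 <- sweep(Z1, 2L, ctr)
  M2 <- sweep(Z2, 2L, ctr)
  mean(tcrossprod(M1, M2)) / denom
}

#' Mean self-relationship of a population
#'
#' Mean of the diagonal of the VanRaden relationship matrix (each member's
#' relationship with itself), used as the base-population scaling constant
#' for relationship metrics: when allele frequencies are estimated from the
#' population itself, the cross-block mean over that population is exactly
#' zero by centering, so the diagonal mean is the stable positive reference.
#'
#' @param Z dosage matrix (individuals x markers).
#' @param base_freq alternative-allele frequencies of the base population.
#' @return a single positive numeric value.
#' @export
mean_self_relationship <- function(Z, base_freq) {
  denom <- 2 * sum(base_freq * (1 - base_freq))
  if (denom <= 0)
    stop("all base-population allele frequencies are 0 or 1: relationship undefined")
  M <- sweep(Z, 2L, 2 * (base_freq - 0.5))
  mean(rowSums(M^2)) / denom
}

new_pop_ids <- function(cycle, n) sprintf("C%02d_%05d", cycle, seq_len(n))

# initialize one simulation run: founders -> initial cross -> F1 -> SSD ->
# cycle-1 breeding population, phenotype model, initial TP and model fit
init_state <- function(config) {
  f <- config$founders
  founders <- if (inherits(f, "founder_set")) f
    else if (!is.null(f$genotype_path))
      read_founders(f$genotype_path, f$map_path, f$phenotype_path)
    else do.call(generate_synthetic_founders, f)

  qtl <- build_qtl_model(founders, config$L)
  plan <- initial_cross(founders, config$n_couples)
  fpop <- founders$haplotypes
  f1 <- cross(fpop, cbind(plan$P1, plan$P2), config$offspring_per_couple)
  pop <- single_seed_descent(f1, config$ssd_generations)
  pop$ids <- new_pop_ids(1L, n_ind(pop))

  g_ref <- if (config$var_g_reference == "f3") genetic_value(pop, qtl)
           else genetic_value(fpop, qtl)
  pheno <- build_phenotype_model(g_ref, config$h2, config$n_env)

  marker_idx <- qtl$marker_idx
  base_Z <- dosages(fpop, marker_idx)
  base_freq <- allele_freq(fpop)[marker_idx]     # allele-1 ("alternative") freq
  base_rel <- mean_self_relationship(base_Z, base_freq)

  tp_ids <- if (config$tp$protocol == "oracle" || config$tp$initial == "random")
    sort(sample(fpop$ids, min(config$tp$initial_size, n_ind(fpop))))
  else fpop$ids
  sel <- match(tp_ids, fpop$ids)
  tp <- training_set(base_Z[sel, , drop = FALSE], founders$phenotypes[sel],
                     rep(0L, length(sel)), tp_ids)
  model <- fit_rrblup(tp)

  list(cycle = 0L, pop = pop, qtl = qtl, pheno = pheno, tp = tp,
       model = model, base_freq = base_freq, base_rel = base_rel,
       marker_idx = marker_idx, config = config)
}

chimeric_N <- function(ramp, cycle) {
  N <- 0L
  for (bp in ramp) if (cycle >= bp[1L]) N <- as.integer(bp[2L])
  N
}

#' Advance one breeding cycle
#'
#' Event order within a cycle: (1) update the training population
#' (phenotyping its new entries) and refit the prediction model, (2)
#' predict GEBVs of the breeding population, (3) select and couple parents,
#' (4) cross the couples, (5) single-seed descent to the next breeding
#' population, (6) record metrics. The top/tails/random update is driven by
#' the previous model's GEBVs; the model is then refit before selection.
#'
#' @param state simulation state from `init_state()` / a previous cycle.
#' @return the updated state, with `state$metrics` holding this cycle's
#'   metrics row.
#' @keywords internal
run_cycle <- function(state) {
  config <- state$config
  cyc <- state$cycle + 1L
  pop <- state$pop
  qtl <- state$qtl
  pop_Z <- dosages(pop, state$marker_idx)
  g_true <- stats::setNames(genetic_value(pop, qtl), pop$ids)

  ## (1) TP update + model refit
  tpcfg <- config$tp
  gebvs_prev <- predict_gebv(state$model, pop_Z)
  n_added <- 0L; n_removed <- 0L; resid_err <- NA_real_
  if (tpcfg$protocol == "standard") {
    up <- standard_update(state$tp, pop_Z, gebvs_prev, g_true, state$pheno,
                          tpcfg$method, tpcfg$n_add, tpcfg$n_drop_oldest, cyc)
    state$tp <- up$tp
    state$model <- fit_rrblup(state$tp)
  } else if (tpcfg$protocol == "criterion") {
    up <- criterion_update(state$tp, pop_Z, g_true, state$pheno, state$model,
                           tpcfg$method, tpcfg$n_add, tpcfg$n_drop_oldest, cyc)
    state$tp <- up$tp
    state$model <- fit_rrblup(state$tp)
  } else if (tpcfg$protocol == "oracle") {
    up <- oracle_tp_update(state$tp, pop_Z, g_true, state$pheno, cyc,
                           tpcfg$max_add, tpcfg$max_remove, tpcfg$refit_every)
    state$tp <- up$tp
    state$model <- up$model
  } else up <- NULL
  if (!is.null(up)) {
    n_added <- length(up$report$added); n_removed <- length(up$report$removed)
    if (n_added > 0L) {
      add <- up$report$added
      yi <- state$tp$y[match(add, state$tp$ids)]
      resid_err <- mean(abs(g_true[add] - yi))
    }
  }

  ## (2) GEBVs for selection and metrics
  gebvs <- predict_gebv(state$model, pop_Z)

  ## (3) parental selection
  sel <- config$selection
  plan <- switch(sel$method,
    truncation = truncation_select(gebvs, config$n_parents),
    scoping = scoping_select(pop_Z, gebvs, sel$SR, config$n_parents),
    chimeric = chimeric_scoping_select(pop_Z, gebvs,
                                       chimeric_N(sel$chimeric_ramp, cyc),
                                       sel$SR, config$n_parents),
    oracle = oracle_parent_select(pop, qtl, config$n_parents))

  ## (4)-(5) cross and single-seed descent
  f1 <- cross(pop, cbind(plan$P1, plan$P2), config$offspring_per_couple)
  new_pop <- single_seed_descent(f1, config$ssd_generations)
  new_pop$ids <- new_pop_ids(cyc + 1L, n_ind(new_pop))

  ## (6) metrics (on the population GEBVs were predicted for)
  g_resc <- g_true / qtl$denom
  top10 <- mean(sort(g_resc, decreasing = TRUE)[seq_len(min(10L, length(g_resc)))])
  perf <- if (stats::sd(gebvs) > 0 && stats::sd(g_true) > 0)
    stats::cor(gebvs, g_true) else NA_real_
  rel <- genetic_relationship(state$tp$Z, pop_Z, state$base_freq) / state$base_rel
  state$metrics <- data.frame(
    cycle = cyc,
    top10_value = top10,
    mean_value = mean(g_resc),
    max_reachable = max_reachable_value(pop, qtl),
    fixed_value = fixed_genetic_value(pop, qtl),
    predictive_performance = perf,
    relationship = rel,
    residual_error = resid_err,
    tp_size = nrow(state$tp$Z),
    n_added = n_added,
    n_removed = n_removed)

  state$cycle <- cyc
  state$pop <- new_pop
  state
}

#' Run a replicated breeding-program experiment
#'
#' Runs `n_runs` independent replicates of the configured breeding program,
#' each seeded with `seed + run` so that experiments sharing a master seed
#' are paired at the founder/QTL level across selection methods. Returns
#' the raw per-run, per-cycle metrics and their across-run mean and
#' standard error.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-run progress?
#' @return a list of class `gs_experiment` with elements `raw` (data frame:
#'   run, cycle, metrics) and `summary` (per-cycle mean and standard error
#'   of every metric).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  raw <- vector("list", config$n_runs)
  for (run in seq_len(config$n_runs)) {
    set.seed(config$seed + run)
    state <- init_state(config)
    rows <- vector("list", config$n_cycles)
    for (cyc in seq_len(config$n_cycles)) {
      state <- run_cycle(state)
      rows[[cyc]] <- state$metrics
    }
    raw[[run]] <- cbind(run = run, do.call(rbind, rows))
    if (verbose) message("run ", run, "/", config$n_runs, " done")
  }
  raw <- do.call(rbind, raw)
  metric_cols <- setdiff(names(raw), c("run", "cycle"))
  agg_mean <- stats::aggregate(raw[metric_cols], by = raw["cycle"], FUN = mean,
                               na.rm = TRUE)
  se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  agg_se <- stats::aggregate(raw[metric_cols], by = raw["cycle"], FUN = se)
  names(agg_se)[-1L] <- paste0(names(agg_se)[-1L], "_se")
  structure(list(raw = raw, summary = merge(agg_mean, agg_se, by = "cycle")),
            class = "gs_experiment")
}

#' @export
print.gs_experiment <- function(x, ...) {
  n_runs <- length(unique(x$raw$run))
  last <- x$summary[which.max(x$summary$cycle), ]
  cat("Breeding-program experiment:", n_runs, "run(s) x",
      max(x$raw$cycle), "cycles\n")
  cat(sprintf("  final cycle: top-10 value %.3f, max reachable %.3f, predictive performance %.3f\n",
              last$top10_value, last$max_reachable, last$predictive_performance))
  invisible(x)
}

#' Run several selection methods on paired seeds
#'
#' Executes `run_experiment()` once per method, sharing the master seed so
#' that founders, QTL model and cycle-1 population are identical across
#' methods within each run.
#'
#' @param config a base [experiment_config()].
#' @param methods named list: each element is a list of config overrides
#'   (`selection` and/or `tp` sub-lists) applied on top of `config`.
#' @param verbose print progress?
#' @return a data frame of raw metrics with a `method` column.
#' @export
compare_methods <- function(config, methods, verbose = FALSE) {
  out <- lapply(names(methods), function(mname) {
    cfg <- config
    ov <- methods[[mname]]
    if (!is.null(ov$selection))
      cfg$selection <- utils::modifyList(cfg$selection, ov$selection)
    if (!is.null(ov$tp)) cfg$tp <- utils::modifyList(cfg$tp, ov$tp)
    if (verbose) message("method: ", mname)
    cbind(method = mname, run_experiment(cfg, verbose = verbose)$raw)
  })
  do.call(rbind, out)
}

#' Write experiment metrics as tidy CSV
#'
#' Long format: run, cycle, (method,) metric, value.
#'
#' @param x a `gs_experiment` or the data frame from [compare_methods()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_metrics <- function(x, path) {
  df <- if (inherits(x, "gs_experiment")) x$raw else x
  idc <- intersect(c("method", "run", "cycle"), names(df))
  long <- stats::reshape(df, direction = "long",
                         varying = setdiff(names(df), idc),
                         v.names = "value", timevar = "metric",
                         times = setdiff(names(df), idc), idvar = idc)
  rownames(long) <- NULL
  utils::write.csv(long[order(long[[idc[1L]]], long$cycle), ], path,
                   row.names = FALSE)
  invisible(path)
}
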