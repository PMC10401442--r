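#' Training-population update report
#'
#' Bookkeeping record returned by every TP update: ids added and removed,
#' the resulting TP size and, for the greedy oracle optimizer, the per-step
#' predictive-performance trace.
#'
#' @keywords internal
tp_report <- function(added, removed, tp_size_after, trace = NULL) {
  structure(list(added = added, removed = removed,
                 tp_size_after = tp_size_after, trace = trace),
            class = "tp_report")
}

#' @export
print.tp_report <- function(x, ...) {
  cat("TP update: +", length(x$added), " / -", length(x$removed),
      " -> size ", x$tp_size_after, "\n", sep = "")
  invisible(x)
}

# drop the n earliest-entry members (ties by ascending id)
tp_drop_oldest <- function(tp, n_drop) {
  if (n_drop <= 0L) return(list(tp = tp, removed = character(0)))
  n_drop <- min(n_drop, nrow(tp$Z))
  ord <- order(tp$entry_cycle, tp$ids)
  drop <- ord[seq_len(n_drop)]
  list(tp = training_set(tp$Z[-drop, , drop = FALSE], tp$y[-drop],
                         tp$entry_cycle[-drop], tp$ids[-drop]),
       removed = tp$ids[drop])
}

tp_append <- function(tp, Z_new, y_new, ids_new, cycle) {
  training_set(rbind(tp$Z, Z_new), c(tp$y, y_new),
               c(tp$entry_cycle, rep(as.integer(cycle), length(ids_new))),
               c(tp$ids, ids_new))
}

#' Standard training-population update (top / tails / random)
#'
#' Removes the `n_drop_oldest` earliest-entry members, then adds `n_add`
#' individuals from the breeding population: `top` takes the highest GEBVs,
#' `tails` takes `n_add/2` highest plus `n_add/2` lowest, `random` samples
#' uniformly without replacement. Added individuals are phenotyped in one
#' batch and tagged with the current cycle.
#'
#' @param tp a [training_set()].
#' @param pop_geno marker dosage matrix of the breeding population
#'   (rownames = ids).
#' @param gebvs named GEBV vector over the breeding population.
#' @param g_true named true genetic values (for phenotyping the additions).
#' @param pheno_model a `phenotype_model`.
#' @param method one of `"top"`, `"tails"`, `"random"`.
#' @param n_add number of individuals to add.
#' @param n_drop_oldest number of oldest members to remove first.
#' @param cycle current cycle index (entry tag for additions).
#' @return a list with elements `tp` (the updated `training_set`) and
#'   `report` (a `tp_report`).
#' @export
standard_update <- function(tp, pop_geno, gebvs, g_true, pheno_model,
                            method = c("top", "tails", "random"),
                            n_add, n_drop_oldest, cycle) {
  method <- match.arg(method)
  ids <- rownames(pop_geno)
  pool <- setdiff(ids, tp$ids)
  if (n_add > length(pool)) stop("population smaller than n_add")
  if (method == "tails" && n_add %% 2L != 0L) stop("tails needs an even n_add")
  dr <- tp_drop_oldest(tp, n_drop_oldest)
  tp2 <- dr$tp
  add <- if (n_add == 0L) character(0) else switch(method,
    top = pool[order_by_score(gebvs[pool], pool)][seq_len(n_add)],
    tails = {
      ord <- pool[order_by_score(gebvs[pool], pool)]
      c(utils::head(ord, n_add / 2L), utils::tail(ord, n_add / 2L))
    },
    random = sample(pool, n_add))
  if (length(add)) {
    y_add <- simulate_phenotypes(g_true[add], pheno_model)
    tp2 <- tp_append(tp2, pop_geno[add, , drop = FALSE], y_add, add, cycle)
  }
  list(tp = tp2, report = tp_report(add, dr$removed, nrow(tp2$Z)))
}

# mean PEV (or mean CD) over target contrasts for a provisional TP genotype
# matrix, at fixed variance components
mean_criterion_value <- function(Ztp, model, target_geno, method) {
  fake_tp <- list(Z = Ztp)
  pc <- pev_core(fake_tp, model, target_geno)
  if (method == "pevmean") mean(pc$pev)
  else mean(ifelse(pc$ctc <= 0, 1, 1 - pc$pev / (model$sigma_u2 * pc$ctc)))
}

#' Criterion-based training-population update (PEVmean / CDmean)
#'
#' Greedy forward selection of `n_add` breeding-population members that
#' minimize the mean prediction error variance (`pevmean`) or maximize the
#' mean reliability (`cdmean`) of the remaining breeding population's
#' contrasts, recomputed after every accepted member at the fixed variance
#' components of `model`.
#'
#' @inheritParams standard_update
#' @param model the `rrblup_model` fitted on `tp` (supplies the variance
#'   components; phenotypes are not needed to score candidates).
#' @param method `"pevmean"` or `"cdmean"`.
#' @return a list with elements `tp` and `report`.
#' @export
criterion_update <- function(tp, pop_geno, g_true, pheno_model, model,
                             method = c("pevmean", "cdmean"),
                             n_add, n_drop_oldest, cycle) {
  method <- match.arg(method)
  ids <- rownames(pop_geno)
  dr <- tp_drop_oldest(tp, n_drop_oldest)
  tp2 <- dr$tp
  chosen <- character(0)
  pool <- setdiff(ids, tp2$ids)
  while (length(chosen) < n_add && length(pool) > 0L) {
    best_id <- NA_character_; best_val <- NA_real_
    for (cand in pool) {
      # the remaining breeding population: everything not (about to be) in the TP
      targets <- setdiff(ids, c(chosen, tp2$ids, cand))
      if (length(targets) == 0L) break
      Zt <- rbind(tp2$Z, pop_geno[c(chosen, cand), , drop = FALSE])
      val <- mean_criterion_value(Zt, model, pop_geno[targets, , drop = FALSE],
                                  method)
      better <- if (is.na(best_val)) TRUE
                else if (method == "pevmean") val < best_val else val > best_val
      # deterministic tie rule: first (ascending-id) candidate wins ties
      if (better) { best_val <- val; best_id <- cand }
    }
    chosen <- c(chosen, best_id)
    pool <- setdiff(pool, best_id)
  }
  if (length(chosen)) {
    y_add <- simulate_phenotypes(g_true[chosen], pheno_model)
    tp2 <- tp_append(tp2, pop_geno[chosen, , drop = FALSE], y_add, chosen, cycle)
  }
  list(tp = tp2, report = tp_report(chosen, dr$removed, nrow(tp2$Z)))
}

# Pearson correlation of each column of M with x; NA-safe, returns -Inf for
# degenerate columns so they can never win an improvement comparison
safe_cor <- function(x, M) {
  if (length(x) < 3L || stats::sd(x) == 0) return(rep(-Inf, ncol(M)))
  r <- suppressWarnings(as.numeric(stats::cor(x, M)))
  r[!is.finite(r)] <- -Inf
  r
}

# GEBV predictions for an evaluation set through the kernel form, with GLS
# intercept, at fixed lambda:
#   g_hat = Zev Zt' (Zt Zt' + lambda I)^-1 (y - beta 1)
kernel_predict <- function(Zt, y, lambda, Zev) {
  K <- tcrossprod(Zt)
  diag(K) <- diag(K) + lambda
  A <- chol2inv(chol(K))
  q <- as.numeric(A %*% rep(1, nrow(Zt)))
  wy <- as.numeric(A %*% y)
  beta <- sum(wy) / sum(q)
  as.numeric(Zev %*% crossprod(Zt, wy - beta * q))
}

#' Oracle training-population update
#'
#' Greedy add--remove optimization of the training population against the
#' ground truth: the predictive performance is the Pearson correlation
#' between GEBVs and true genetic values over the evaluation set (the
#' breeding population minus every individual accepted into the TP this
#' cycle). Each iteration first evaluates adding every breeding-population
#' member not yet in the TP and accepts the best candidate if it strictly
#' improves the performance; it then evaluates removing every current TP
#' member (excluding this cycle's additions) and removes the best if that
#' strictly improves the performance. Iteration stops when neither step
#' improves or when both caps are exhausted, so the TP may grow, shrink or
#' keep its size.
#'
#' Candidate additions are scored with exact solver refits at fixed
#' variance ratio `lambda` via rank-one block-inverse updates (one matrix
#' multiply per sweep); `lambda` is re-estimated by full REML at loop start
#' and after every `refit_every` accepted changes (`refit_every = 1`
#' restores full-REML-per-step audit mode).
#'
#' @inheritParams standard_update
#' @param max_add,max_remove caps on additions and removals (default 50).
#' @param refit_every accepted-change interval between REML refits.
#' @param tol strict-improvement tolerance (default 1e-10).
#' @return a list with elements `tp`, `report` and `model` (the final
#'   REML-refit `rrblup_model`).
#' @export
oracle_tp_update <- function(tp, pop_geno, g_true, pheno_model, cycle,
                             max_add = 50L, max_remove = 50L,
                             refit_every = 10L, tol = 1e-10) {
  ids <- rownames(pop_geno)
  y_pop <- simulate_phenotypes(g_true[ids], pheno_model)

  Zt <- tp$Z; yt <- tp$y; idt <- tp$ids; ent <- tp$entry_cycle
  added <- character(0); removed <- character(0)
  trace <- list()
  lambda <- fit_rrblup(training_set(Zt, yt, ent, idt))$lambda
  since_refit <- 0L

  eval_ids <- function() setdiff(ids, added)
  perf_of <- function(Z, y, ev) {
    g_hat <- kernel_predict(Z, y, lambda, pop_geno[ev, , drop = FALSE])
    r <- safe_cor(g_true[ev], matrix(g_hat, ncol = 1L))
    if (!is.finite(r)) warning("degenerate evaluation set: performance undefined")
    r
  }

  ev <- eval_ids()
  perf <- perf_of(Zt, yt, ev)

  repeat {
    progressed <- FALSE

    ## --- addition sweep (vectorized block-inverse refits at fixed lambda)
    cand <- setdiff(ids, c(idt, added))
    if (length(added) < max_add && length(cand) > 0L && length(ev) >= 3L) {
      n <- nrow(Zt)
      K <- tcrossprod(Zt); diag(K) <- diag(K) + lambda
      A <- chol2inv(chol(K))
      q <- as.numeric(A %*% rep(1, n)); wy <- as.numeric(A %*% yt)
      S11 <- sum(q); S1y <- sum(wy)
      Zc <- pop_geno[cand, , drop = FALSE]
      yc <- y_pop[cand]
      Kx <- tcrossprod(Zt, Zc)                     # n x Nc
      V <- A %*% Kx
      s <- rowSums(Zc^2) + lambda
      gam <- 1 / pmax(s - colSums(Kx * V), 1e-12)
      v1 <- colSums(V); vy <- colSums(V * yt)
      S11c <- S11 + gam * (v1 - 1)^2
      S1yc <- S1y + gam * (v1 - 1) * (vy - yc)
      betac <- S1yc / S11c
      tc <- gam * ((yc - vy) - betac * (1 - v1))
      Zev <- pop_geno[ev, , drop = FALSE]
      Cet <- tcrossprod(Zev, Zt)                   # n_ev x n
      Py <- as.numeric(Cet %*% wy); P0 <- as.numeric(Cet %*% q)
      Qv <- Cet %*% V                              # n_ev x Nc
      Cec <- tcrossprod(Zev, Zc)                   # n_ev x Nc
      Ghat <- (Py - outer(rep(1, length(ev)), betac) * P0) -
        sweep(Qv - Cec, 2L, tc, `*`)
      r <- safe_cor(g_true[ev], Ghat)
      best <- order(-r, cand)[1L]
      if (r[best] > perf + tol) {
        pick <- cand[best]
        perf_before <- perf; perf_eval <- r[best]
        Zt <- rbind(Zt, pop_geno[pick, , drop = FALSE])
        yt <- c(yt, y_pop[[pick]]); idt <- c(idt, pick)
        ent <- c(ent, as.integer(cycle))
        added <- c(added, pick)
        since_refit <- since_refit + 1L
        progressed <- TRUE
        ev <- eval_ids()
        if (since_refit >= refit_every) {
          lambda <- fit_rrblup(training_set(Zt, yt, ent, idt))$lambda
          since_refit <- 0L
        }
        perf <- perf_of(Zt, yt, ev)
        trace[[length(trace) + 1L]] <-
          data.frame(step = length(trace) + 1L, action = "add", id = pick,
                     perf_before = perf_before, perf_eval = perf_eval,
                     perf = perf, stringsAsFactors = FALSE)
      }
    }

    ## --- removal sweep (inverse downdates; this cycle's additions excluded)
    rem_pool <- which(!(idt %in% added))
    if (length(removed) < max_remove && length(rem_pool) > 0L &&
        nrow(Zt) > 3L && length(ev) >= 3L) {
      n <- nrow(Zt)
      K <- tcrossprod(Zt); diag(K) <- diag(K) + lambda
      A <- chol2inv(chol(K))
      q <- as.numeric(A %*% rep(1, n)); wy <- as.numeric(A %*% yt)
      S11 <- sum(q); S1y <- sum(wy)
      Zev <- pop_geno[ev, , drop = FALSE]
      Cet <- tcrossprod(Zev, Zt)
      X <- matrix(0, n, length(rem_pool))
      for (jj in seq_along(rem_pool)) {
        i <- rem_pool[jj]
        Aii <- A[i, i]; ai <- A[, i]
        S11i <- S11 - 2 * q[i] + Aii - (q[i] - Aii)^2 / Aii
        S1yi <- S1y - wy[i] - q[i] * yt[i] + Aii * yt[i] -
          (q[i] - Aii) * (wy[i] - Aii * yt[i]) / Aii
        bi <- S1yi / S11i
        b_i <- yt[i] - bi                  # removed entry of (y - beta 1)
        u <- wy - bi * q - ai * b_i
        kap <- ((wy[i] - bi * q[i]) - Aii * b_i) / Aii
        x <- u - ai * kap
        x[i] <- 0
        X[, jj] <- x
      }
      Ghat <- Cet %*% X
      r <- safe_cor(g_true[ev], Ghat)
      best <- order(-r, idt[rem_pool])[1L]
      if (r[best] > perf + tol) {
        i <- rem_pool[best]
        pick <- idt[i]
        perf_before <- perf; perf_eval <- r[best]
        Zt <- Zt[-i, , drop = FALSE]; yt <- yt[-i]; idt <- idt[-i]; ent <- ent[-i]
        removed <- c(removed, pick)
        since_refit <- since_refit + 1L
        progressed <- TRUE
        if (since_refit >= refit_every) {
          lambda <- fit_rrblup(training_set(Zt, yt, ent, idt))$lambda
          since_refit <- 0L
        }
        perf <- perf_of(Zt, yt, ev)
        trace[[length(trace) + 1L]] <-
          data.frame(step = length(trace) + 1L, action = "remove", id = pick,
                     perf_before = perf_before, perf_eval = perf_eval,
                     perf = perf, stringsAsFactors = FALSE)
      }
    }

    if (!progressed) break
    if (length(added) >= max_add && length(removed) >= max_remove) break
  }

  tp_out <- training_set(Zt, yt, ent, idt)
  model <- fit_rrblup(tp_out)
  list(tp = tp_out,
       report = tp_report(added, removed, nrow(Zt),
                          trace = if (length(trace)) do.call(rbind, trace) else NULL),
       model = model)
}

#' Write a training-set snapshot as TSV
#'
#' One row per member: id, entry cycle, phenotype, then marker dosages.
#'
#' @param tp a `training_set`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tp_snapshot <- function(tp, path) {
  df <- data.frame(id = tp$ids, entry_cycle = tp$entry_cycle, phenotype = tp$y,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(tp$Z))
  names(df)[-(1:3)] <- sprintf("m%d", seq_len(ncol(tp$Z)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
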