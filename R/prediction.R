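#' Training set for genomic prediction
#'
#' Genotype dosages at the marker loci, phenotypes and cycle-of-entry tags
#' for the individuals currently used to fit the prediction model.
#'
#' @param Z numeric matrix (individuals x markers) of dosages in \{-1,0,1\}.
#' @param y numeric phenotype vector aligned with the rows of `Z`.
#' @param entry_cycle integer cycle in which each individual entered the
#'   training set (used for oldest-first removal).
#' @param ids unique individual identifiers.
#' @return An object of class `training_set`.
#' @export
training_set <- function(Z, y, entry_cycle, ids) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (length(y) != n || length(entry_cycle) != n || length(ids) != n)
    stop("Z rows, y, entry_cycle and ids must be aligned")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated ids in training set")
  dimnames(Z) <- NULL
  structure(list(Z = Z, y = as.numeric(y),
                 entry_cycle = as.integer(entry_cycle), ids = ids),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("Training set:", nrow(x$Z), "individuals x", ncol(x$Z), "markers; entry cycles",
      paste(range(x$entry_cycle), collapse = "-"), "\n")
  invisible(x)
}

# REML machinery: profile likelihood over lambda = sigma_e2 / sigma_u2 using
# the spectral decomposition of the (fixed-effect-projected) marker kernel.
# One eigendecomposition per fit; each lambda evaluation is O(n).
reml_spectral <- function(Z, y) {
  n <- length(y)
  qr1 <- qr(matrix(1, n, 1))
  Tm <- qr.Q(qr1, complete = TRUE)[, -1L, drop = FALSE]   # basis of 1-perp
  K <- tcrossprod(Z)
  Kt <- crossprod(Tm, K %*% Tm)
  es <- eigen((Kt + t(Kt)) / 2, symmetric = TRUE)
  eta <- as.numeric(crossprod(es$vectors, crossprod(Tm, y)))
  d <- pmax(es$values, 0)
  list(d = d, eta2 = eta^2, nm = n - 1L)
}

reml_neg2ll <- function(log_lambda, sp) {
  lam <- exp(log_lambda)
  dl <- sp$d + lam
  sum(log(dl)) + sp$nm * log(sum(sp$eta2 / dl))
}

#' Fit ridge-regression BLUP by REML
#'
#' Fits the mixed model `y = 1 beta + Z u + eps` with `u ~ N(0, sigma_u2 I)`
#' and `eps ~ N(0, sigma_e2 I)`. The restricted likelihood is profiled down
#' to the single ratio `lambda = sigma_e2 / sigma_u2` using the spectral
#' decomposition of the marker kernel `Z Z'` (after projecting out the
#' intercept), and maximized by bounded scalar search over
#' `log(lambda) in [-10, 10]` with tolerance 1e-8. The intercept is the
#' generalized-least-squares estimate at the optimum and the marker effects
#' are `u = Z' (Z Z' + lambda I)^{-1} (y - beta)`. All markers are retained,
#' including monomorphic ones (the ridge system is full rank for
#' `lambda > 0`).
#'
#' @param tp a [training_set()].
#' @param lambda optional fixed variance ratio; when supplied, REML is
#'   skipped and the solution is computed at this ratio (`sigma_u2` is then
#'   estimated at the fixed ratio).
#' @return An object of class `rrblup_model`: `beta`, `u`, `sigma_u2`,
#'   `sigma_e2`, `lambda`, `boundary` (TRUE when the optimum hit the search
#'   bound), `n`, `k`.
#' @export
fit_rrblup <- function(tp, lambda = NULL) {
  Z <- tp$Z; y <- tp$y
  n <- length(y)
  if (n < 3L) stop("training set must contain at least 3 individuals")
  if (stats::var(y) == 0) stop("phenotypes have zero variance")
  sp <- reml_spectral(Z, y)
  boundary <- FALSE
  if (is.null(lambda)) {
    opt <- stats::optimize(reml_neg2ll, c(-10, 10), sp = sp, tol = 1e-8)
    lambda <- exp(opt$minimum)
    boundary <- min(abs(opt$minimum - c(-10, 10))) < 1e-3
  }
  sigma_u2 <- sum(sp$eta2 / (sp$d + lambda)) / sp$nm
  H <- tcrossprod(Z)
  diag(H) <- diag(H) + lambda
  ch <- chol(H)
  Hi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  Hiy <- backsolve(ch, forwardsolve(t(ch), y))
  beta <- sum(Hiy) / sum(Hi1)
  u <- as.numeric(crossprod(Z, Hiy - beta * Hi1))
  structure(list(beta = beta, u = u, sigma_u2 = sigma_u2,
                 sigma_e2 = lambda * sigma_u2, lambda = lambda,
                 boundary = boundary, n = n, k = ncol(Z)),
            class = "rrblup_model")
}

#' @export
print.rrblup_model <- function(x, ...) {
  cat(sprintf("rrBLUP model: n = %d, k = %d, lambda = %.4g (sigma_u2 = %.4g, sigma_e2 = %.4g)%s\n",
              x$n, x$k, x$lambda, x$sigma_u2, x$sigma_e2,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Genome-wide estimated breeding values
#'
#' `g_hat = Z u_hat`; no intercept is added, so GEBVs are centered breeding
#' values (rankings are invariant to the intercept).
#'
#' @param model an `rrblup_model`.
#' @param genotypes dosage matrix (individuals x markers).
#' @return numeric vector of GEBVs, named by the matrix row names.
#' @export
predict_gebv <- function(model, genotypes) {
  if (ncol(genotypes) != model$k)
    stop("genotype matrix has ", ncol(genotypes), " markers; model expects ", model$k)
  g <- as.numeric(genotypes %*% model$u)
  names(g) <- rownames(genotypes)
  g
}

# shared PEV machinery: contrast of each candidate's GEBV against the TP
# mean, computed through the n-space form of the absorbed mixed-model
# equations, sigma_e2 * c' (Zc' Zc + lambda I)^-1 c with Zc the
# column-centered TP genotypes (intercept absorbed).
pev_core <- function(tp, model, candidates) {
  Zc <- sweep(tp$Z, 2L, colMeans(tp$Z))
  C <- sweep(as.matrix(candidates), 2L, colMeans(tp$Z))   # contrasts vs TP mean
  Kc <- tcrossprod(Zc)
  diag(Kc) <- diag(Kc) + model$lambda
  V <- Zc %*% t(C)
  ctc <- rowSums(C^2)
  quad <- colSums(V * solve(Kc, V))
  pev <- model$sigma_e2 * (ctc - quad) / model$lambda
  list(pev = pmax(pev, 0), ctc = ctc)
}

#' Prediction error variance of candidate contrasts
#'
#' PEV of the contrast between each candidate's GEBV and the training-set
#' mean, from the inverse coefficient matrix of the mixed-model equations at
#' the fitted variance components (intercept absorbed).
#'
#' @param tp a `training_set`.
#' @param model the `rrblup_model` fitted on `tp`.
#' @param candidates dosage matrix (candidates x markers).
#' @return numeric vector of PEVs (>= 0).
#' @export
prediction_error_variance <- function(tp, model, candidates) {
  pev_core(tp, model, candidates)$pev
}

#' Reliability (coefficient of determination) of candidate contrasts
#'
#' `CD = 1 - PEV / (sigma_u2 * c'c)` per candidate contrast, bounded in
#' \[0, 1\]. A zero-length contrast (candidate identical to the TP mean) has
#' reliability 1 by convention.
#'
#' @inheritParams prediction_error_variance
#' @return numeric vector of reliabilities in \[0, 1\].
#' @export
reliability <- function(tp, model, candidates) {
  pc <- pev_core(tp, model, candidates)
  cd <- ifelse(pc$ctc <= 0, 1, 1 - pc$pev / (model$sigma_u2 * pc$ctc))
  pmin(pmax(cd, 0), 1)
}

#' Write / read an rrBLUP model as a key-value text artifact
#'
#' Plain-text dump (one `key<TAB>value` pair per line; the marker-effect
#' vector as comma-separated values) for reproducibility audits.
#'
#' @param model an `rrblup_model`.
#' @param path output (input) file path.
#' @return `write_rrblup` returns the path invisibly; `read_rrblup` returns
#'   an `rrblup_model`.
#' @export
write_rrblup <- function(model, path) {
  lines <- c(
    sprintf("beta\t%.17g", model$beta),
    sprintf("lambda\t%.17g", model$lambda),
    sprintf("sigma_u2\t%.17g", model$sigma_u2),
    sprintf("sigma_e2\t%.17g", model$sigma_e2),
    sprintf("boundary\t%d", as.integer(model$boundary)),
    sprintf("n\t%d", model$n),
    sprintf("k\t%d", model$k),
    paste0("u\t", paste(sprintf("%.17g", model$u), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rrblup
#' @export
read_rrblup <- function(path) {
  kv <- strsplit(readLines(path), "\t", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  structure(list(beta = as.numeric(vals[["beta"]]),
                 u = as.numeric(strsplit(vals[["u"]], ",", fixed = TRUE)[[1L]]),
                 sigma_u2 = as.numeric(vals[["sigma_u2"]]),
                 sigma_e2 = as.numeric(vals[["sigma_e2"]]),
                 lambda = as.numeric(vals[["lambda"]]),
                 boundary = as.logical(as.integer(vals[["boundary"]])),
                 n = as.integer(vals[["n"]]), k = as.integer(vals[["k"]])),
            class = "rrblup_model")
}
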