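#' Multi-environment phenotype model with frozen variance components
#'
#' Calibrates the variance components of the phenotype simulation from the
#' genetic variance `var_g0` of the breeding population before the first
#' cycle. Phenotyping happens in `n_env` environments (default 3): an
#' environment main effect `e_j ~ N(0, sigmaE2)` shared by every individual
#' of the batch, plus an individual residual `eps_ij ~ N(0, sigmaR2)`. The
#' components are fixed by
#' \deqn{\sigma_E^2 = 8\,var(g_0), \qquad
#'       \sigma_R^2 = n_{env}\,(var(g_0)/h^2 - var(g_0)),}
#' which yields a realized narrow-sense heritability of `h2` on the
#' across-environment phenotype mean. Both components are frozen at
#' construction and never updated during a simulation.
#'
#' @param genetic_values numeric vector of genetic values of the reference
#'   (pre-cycle-1) breeding population; its population variance becomes
#'   `var_g0`.
#' @param h2 target heritability in (0, 1].
#' @param n_env number of environments (default 3).
#' @return An object of class `phenotype_model` with fields `sigmaE2`,
#'   `sigmaR2`, `n_env`, `h2`, `var_g0`.
#' @export
build_phenotype_model <- function(genetic_values, h2 = 0.5, n_env = 3L) {
  if (length(unique(genetic_values)) < 2L)
    stop("degenerate genetic variance: need >= 2 distinct genetic values")
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  n <- length(genetic_values)
  var_g0 <- stats::var(genetic_values) * (n - 1) / n   # population denominator
  if (var_g0 <= 0) stop("degenerate genetic variance")
  structure(list(sigmaE2 = 8 * var_g0,
                 sigmaR2 = n_env * (var_g0 / h2 - var_g0),
                 n_env = as.integer(n_env), h2 = h2, var_g0 = var_g0),
            class = "phenotype_model")
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat(sprintf("Phenotype model: var_g0 = %.4g, sigmaE2 = %.4g, sigmaR2 = %.4g, %d environments, h2 = %.2f\n",
              x$var_g0, x$sigmaE2, x$sigmaR2, x$n_env, x$h2))
  invisible(x)
}

#' Simulate phenotypes for one phenotyping batch
#'
#' Draws one environment effect per environment (shared by all individuals
#' of the batch) and an independent residual per individual and environment;
#' the returned phenotype is the across-environment mean
#' `y_i = mean_j(g_i + e_j + eps_ij)`. Environment effects are redrawn for
#' every batch. Uses the current global RNG stream.
#'
#' @param genetic_values numeric vector of true genetic values.
#' @param model a `phenotype_model`.
#' @return numeric vector of phenotypes, same length and names as
#'   `genetic_values`.
#' @export
simulate_phenotypes <- function(genetic_values, model) {
  n <- length(genetic_values)
  e <- stats::rnorm(model$n_env, 0, sqrt(model$sigmaE2))
  eps <- matrix(stats::rnorm(n * model$n_env, 0, sqrt(model$sigmaR2)),
                n, model$n_env)
  y <- genetic_values + mean(e) + rowMeans(eps)
  names(y) <- names(genetic_values)
  y
}
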