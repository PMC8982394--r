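#' Simulate progeny phenotype counts from the genetic model
#'
#' Independent multinomial draws per cross with probabilities
#' `1/3 + X_i theta` (the forward version of the fitted model).
#'
#' @param theta Six-effect parameter vector (see [parameter_names()]).
#' @param design A `genetic_design`.
#' @param n_per_cross Integer vector of 3 progeny totals (AxB, BxC, AxC).
#' @param seed Optional integer seed for reproducibility.
#' @return A `cross_counts` table, or a plain all-zero table when all
#'   totals are zero.
#' @export
#' @examples
#' simulate_cross_counts(rep(0, 6), n_per_cross = c(300, 300, 300), seed = 1)
simulate_cross_counts <- function(theta, design = default_design(),
                                  n_per_cross = c(400, 300, 370),
                                  seed = NULL) {
  theta <- as_theta(theta)
  if (length(n_per_cross) != 3L || any(n_per_cross < 0)) {
    stop("n_per_cross must be 3 non-negative totals")
  }
  p <- model_probabilities(theta, design)
  if (any(p <= 0 | p >= 1)) {
    stop("theta implies phenotype probabilities outside (0, 1); ",
         "shrink the effects")
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- t(vapply(1:3, function(i) {
    if (n_per_cross[i] == 0) rep(0L, 3L)
    else as.integer(stats::rmultinom(1L, n_per_cross[i], p[i, ]))
  }, integer(3L)))
  dimnames(counts) <- list(cross_levels(), phenotype_levels())
  if (all(n_per_cross > 0)) cross_counts(counts) else counts
}

#' Simulate isotropic spore dispersal distances
#'
#' Colony coordinates drawn as independent Normal(0, sigma^2) x and y
#' components around the membrane center, returned as radial distances.
#' Distances^2 / sigma^2 are then chi-squared with 2 df, i.e. distances
#' follow a Rayleigh(sigma) law with mean `sigma * sqrt(pi / 2)`.
#'
#' @param n_colonies Number of colonies.
#' @param sigma Dispersal kernel scale, cm; must be > 0.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_colonies` distances (cm).
#' @export
#' @examples
#' d <- simulate_dispersal(1000, sigma = 3, seed = 1)
#' mean(d) / (3 * sqrt(pi / 2))  # ~1
simulate_dispersal <- function(n_colonies, sigma, seed = NULL) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (n_colonies < 0) stop("n_colonies must be >= 0")
  if (n_colonies == 0) return(numeric())
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n_colonies, 0, sigma)
  y <- stats::rnorm(n_colonies, 0, sigma)
  radial_distances(cbind(x, y))
}

#' Simulate a germination plating record
#'
#' Replicate colony counts drawn as Binomial(round(expected), rate_true):
#' each plated conidium germinates independently with the true rate.
#'
#' @param rate_true True germination probability in `[0, 1]`.
#' @param expected Expected colony count if all conidia germinated.
#' @param replicates Number of replicate plates (the assay uses 3).
#' @param seed Optional integer seed.
#' @return List with `replicate_colony_counts`, `expected`, `rate_true`.
#' @export
#' @examples
#' simulate_germination(0.5, expected = 100, replicates = 3, seed = 1)
simulate_germination <- function(rate_true, expected, replicates = 3L,
                                 seed = NULL) {
  if (!is.finite(rate_true) || rate_true < 0 || rate_true > 1) {
    stop("rate_true must lie in [0, 1]")
  }
  if (expected <= 0) stop("expected must be positive")
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  list(replicate_colony_counts = stats::rbinom(replicates,
                                               round(expected), rate_true),
       expected = expected, rate_true = rate_true)
}

#' Parameter-recovery experiment for the full epistatic fit
#'
#' Repeatedly simulates progeny counts from the forward model at
#' `theta_true`, refits the full six-parameter model, and aggregates
#' per-parameter bias, RMSE, and the coverage of the nominal 95%
#' information-matrix confidence intervals.
#'
#' @param theta_true True six-effect vector.
#' @param design A `genetic_design`.
#' @param n_per_cross Progeny totals per cross for each replicate.
#' @param n_replicates Number of simulation replicates.
#' @param seed Integer seed (one stream; replicate r uses draw r).
#' @return List of class `recovery_summary`: `summary` data frame (per
#'   parameter: truth, mean estimate, bias, rmse, coverage), `n_failed`,
#'   `n_replicates`.
#' @export
#' @examples
#' recovery_experiment(c(0.06, -0.03, 0.03, 0.03, -0.03, 0),
#'                     n_per_cross = rep(500, 3), n_replicates = 20, seed = 1)
recovery_experiment <- function(theta_true, design = default_design(),
                                n_per_cross = rep(5000L, 3L),
                                n_replicates = 200L, seed = 1L) {
  theta_true <- as_theta(theta_true)
  set.seed(seed)
  est <- matrix(NA_real_, n_replicates, 6L,
                dimnames = list(NULL, parameter_names()))
  cover <- matrix(NA, n_replicates, 6L,
                  dimnames = list(NULL, parameter_names()))
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    counts <- simulate_cross_counts(theta_true, design, n_per_cross)
    fit <- tryCatch(fit_model(counts, design, strict = TRUE),
                    error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    est[r, ] <- fit$theta_hat
    se <- stats::setNames(rep(NA_real_, 6L), parameter_names())
    se[fit$free] <- fit$standard_errors
    cover[r, ] <- abs(fit$theta_hat - theta_true) <= 1.96 * se
  }
  ok <- stats::complete.cases(est)
  summary <- data.frame(
    parameter = parameter_names(),
    truth = unname(theta_true),
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - unname(theta_true),
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            rep(theta_true, each = sum(ok)))^2)),
    coverage = colMeans(cover[ok, , drop = FALSE]),
    row.names = NULL
  )
  structure(list(summary = summary, estimates = est[ok, , drop = FALSE],
                 n_failed = n_failed, n_replicates = n_replicates),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Parameter recovery over %d replicates (%d failed fits):\n",
              x$n_replicates, x$n_failed))
  out <- x$summary
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits)
  print(out, row.names = FALSE)
  invisible(x)
}
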