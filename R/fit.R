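#' Specify a model in the inheritance hierarchy
#'
#' A model is identified by the subset of the six effects constrained to
#' zero. The "environmental" model zeroes all six (no genetic effects); the
#' "full_epistatic" model zeroes none.
#'
#' @param name Model name (free text; the standard hierarchy uses the names
#'   in [hierarchy_specs()]).
#' @param zeroed_params Character vector of parameter names held at zero;
#'   must be a subset of [parameter_names()].
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("additive", c("alpha_beta", "beta_gamma", "alpha_gamma"))
model_spec <- function(name, zeroed_params = character()) {
  zeroed_params <- as.character(zeroed_params)
  bad <- setdiff(zeroed_params, parameter_names())
  if (length(bad)) stop("unknown parameter names: ", paste(bad, collapse = ", "))
  structure(list(name = name, zeroed = unique(zeroed_params)),
            class = "model_spec")
}

#' The standard model hierarchy
#'
#' The ten nested models fitted to the cross progeny counts, from the
#' saturated full epistatic model down to the environmental (no genetic
#' effects) model, together with the parent model each is tested against.
#'
#' @return Named list of `model_spec` objects, each carrying a
#'   `compare_to` attribute naming the more complex model used in the
#'   nested test (`NA` for the full model).
#' @export
hierarchy_specs <- function() {
  mk <- function(name, zeroed, compare_to) {
    s <- model_spec(name, zeroed)
    attr(s, "compare_to") <- compare_to
    s
  }
  list(
    full_epistatic = mk("full_epistatic", character(), NA_character_),
    ab_zero     = mk("ab_zero", "alpha_beta", "full_epistatic"),
    ab_a_zero   = mk("ab_a_zero", c("alpha_beta", "alpha"), "ab_zero"),
    bg_zero     = mk("bg_zero", "beta_gamma", "full_epistatic"),
    bg_b_zero   = mk("bg_b_zero", c("beta_gamma", "beta"), "bg_zero"),
    ab_b_zero   = mk("ab_b_zero", c("alpha_beta", "beta"), "ab_zero"),
    ag_zero     = mk("ag_zero", "alpha_gamma", "full_epistatic"),
    ag_a_zero   = mk("ag_a_zero", c("alpha_gamma", "alpha"), "ag_zero"),
    additive    = mk("additive",
                     c("alpha_beta", "beta_gamma", "alpha_gamma"), "ab_zero"),
    environmental = mk("environmental", parameter_names(), "additive")
  )
}

#' Pearson chi-squared statistic
#'
#' `sum((observed - expected)^2 / expected)` over the table cells.
#'
#' @param observed Matrix of observed counts.
#' @param expected Matrix of expected counts, same shape, all positive.
#' @return The chi-squared statistic (non-negative scalar).
#' @export
#' @examples
#' pearson_chisq(matrix(c(4, 1, 1, 1, 4, 1, 1, 1, 4), 3, byrow = TRUE),
#'               matrix(2, 3, 3))  # 9
pearson_chisq <- function(observed, expected) {
  observed <- as.matrix(observed)
  expected <- as.matrix(expected)
  if (!all(dim(observed) == dim(expected))) {
    stop("observed and expected must have the same shape (got ",
         paste(dim(observed), collapse = "x"), " vs ",
         paste(dim(expected), collapse = "x"), ")")
  }
  if (any(expected <= 0)) stop("all expected counts must be positive")
  sum((observed - expected)^2 / expected)
}

#' Fit an inheritance model by maximum likelihood (IRLS / Fisher scoring)
#'
#' Fits the linear-probability multinomial model `p_i = 1/3 + X_i theta`
#' to the 3 x 3 progeny count table, holding the parameters named in
#' `spec$zeroed` at zero. The score equations are solved by Fisher scoring,
#' which for this model is iteratively reweighted least squares: with
#' observed proportions `y_i` and row totals `n_i`, the score is
#' `U = sum_i n_i X_i' W_i (y_i - p_i)` and the expected information is
#' `I = sum_i n_i X_i' W_i X_i` with `W_i = diag(1/p_ij)` recomputed each
#' iteration (the column-sum-zero design kills the usual rank-one
#' multinomial correction, so `I` is exactly the N X'AX weighting with
#' `A = diag(1/p)`). Steps are halved whenever a fitted probability would
#' leave `(1e-6, 1 - 1e-6)`.
#'
#' @param counts A `cross_counts` table (or 3 x 3 matrix).
#' @param design A `genetic_design`; default [default_design()].
#' @param spec A `model_spec`; default the full epistatic model.
#' @param tol Convergence tolerance on `max|delta theta| / max(1, max|theta|)`.
#' @param max_iter Iteration cap.
#' @param strict If `TRUE`, non-convergence is an error; otherwise the
#'   result is returned flagged with `converged = FALSE`.
#' @return An object of class `inheritance_fit`: list with `spec`,
#'   `theta_hat` (all six parameters, zeroed entries exactly 0),
#'   `fitted_probs` and `expected_counts` (3 x 3), `chisq`, `df`,
#'   `loglik`, `iterations`, `converged`, `standard_errors` (free
#'   parameters only), and `information` (the free-parameter expected
#'   information N X'AX at the optimum).
#' @export
#' @examples
#' fit <- fit_model(f2_counts())
#' fit$chisq   # ~0: the 6-parameter model is saturated on 3 crosses
fit_model <- function(counts, design = default_design(),
                      spec = model_spec("full_epistatic"),
                      tol = 1e-8, max_iter = 100L, strict = FALSE) {
  counts <- cross_counts(counts)
  n_i <- rowSums(counts)
  y <- counts / n_i                     # observed proportions per cross
  free <- setdiff(parameter_names(), spec$zeroed)
  k <- length(free)
  eps <- 1e-6

  xs <- lapply(design$matrices, function(m) m[, free, drop = FALSE])

  probs_for <- function(th_free) {
    th <- stats::setNames(rep(0, 6L), parameter_names())
    th[free] <- th_free
    model_probabilities(th, design)
  }

  theta <- rep(0, k)
  p <- probs_for(theta)                 # theta = 0 -> uniform 1/3
  iter <- 0L
  converged <- k == 0L                  # nothing to estimate: done at once

  if (k > 0L) {
    if (qr(do.call(rbind, xs))$rank < k) {
      stop("design columns for free parameters {",
           paste(free, collapse = ", "), "} are collinear")
    }
    repeat {
      iter <- iter + 1L
      score <- rep(0, k)
      info <- matrix(0, k, k)
      for (i in 1:3) {
        w <- 1 / p[i, ]
        xi <- xs[[i]]
        score <- score + n_i[i] * crossprod(xi, w * (y[i, ] - p[i, ]))
        info <- info + n_i[i] * crossprod(xi, w * xi)
      }
      delta <- tryCatch(solve(info, score), error = function(e) {
        stop("singular information matrix for free parameters {",
             paste(free, collapse = ", "), "}")
      })
      # step-halving keeps all fitted probabilities inside (eps, 1 - eps)
      step <- 1
      repeat {
        cand <- theta + step * delta
        p_cand <- probs_for(cand)
        if (all(p_cand > eps & p_cand < 1 - eps)) break
        step <- step / 2
        if (step < 1e-12) stop("step-halving underflow: fitted probabilities ",
                               "pinned at the boundary")
      }
      moved <- max(abs(step * delta)) / max(1, max(abs(cand)))
      theta <- as.vector(cand)
      p <- p_cand
      if (moved < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    if (!converged && strict) {
      stop("IRLS did not converge in ", max_iter, " iterations")
    }
  }

  theta_hat <- stats::setNames(rep(0, 6L), parameter_names())
  theta_hat[free] <- theta
  expected <- p * n_i
  info_final <- matrix(0, k, k, dimnames = list(free, free))
  if (k > 0L) {
    for (i in 1:3) {
      xi <- xs[[i]]
      info_final <- info_final + n_i[i] * crossprod(xi, (1 / p[i, ]) * xi)
    }
  }
  se <- if (k > 0L) sqrt(diag(solve(info_final))) else numeric()
  structure(list(
    spec = spec,
    theta_hat = theta_hat,
    free = free,
    fitted_probs = p,
    expected_counts = expected,
    chisq = pearson_chisq(counts, expected),
    df = 6L - k,
    loglik = sum(counts * log(p)),
    iterations = iter,
    converged = converged,
    standard_errors = se,
    information = info_final,
    counts = counts
  ), class = "inheritance_fit")
}

#' Fit the environmental (no genetic effects) model
#'
#' All six effects are zero, so every phenotype probability is 1/3 and the
#' expected count in each cell is `n_i / 3`; no iteration is needed. The
#' Pearson chi-squared of this model measures the total variation in the
#' progeny ratios.
#'
#' @param counts A `cross_counts` table (or 3 x 3 matrix).
#' @return An `inheritance_fit` with `df = 6`, zero iterations.
#' @export
#' @examples
#' fit_environmental(f2_counts())$chisq  # 84.27 to two decimals
fit_environmental <- function(counts) {
  fit_model(counts, spec = model_spec("environmental", parameter_names()))
}

#' @export
print.inheritance_fit <- function(x, digits = 4, ...) {
  cat("Inheritance model fit:", x$spec$name, "\n")
  cat(sprintf("  chisq = %.2f on %d df", x$chisq, x$df))
  if (x$df > 0) cat(sprintf(" (P = %.4g)", stats::pchisq(x$chisq, x$df, lower.tail = FALSE)))
  cat("\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (length(x$free)) {
    est <- data.frame(estimate = round(x$theta_hat[x$free], digits),
                      se = round(x$standard_errors, digits))
    print(est)
  } else {
    cat("  no free parameters (environmental model)\n")
  }
  invisible(x)
}

#' Compare two nested model fits
#'
#' The chi-squared-difference test: `delta_chisq = chisq_H0 - chisq_HA` on
#' `delta_df = df_H0 - df_HA` degrees of freedom, with an upper-tail
#' chi-squared p-value. H0 must be strictly nested in HA (HA's zeroed set a
#' proper subset of H0's). A numerically negative difference is clamped to
#' zero with a warning (it cannot occur at exact optima).
#'
#' @param h0,ha `inheritance_fit` objects for the simpler and richer model.
#' @return List of class `nested_comparison`: `h0_name`, `ha_name`,
#'   `delta_chisq`, `delta_chisq_raw`, `delta_df`, `p_value`.
#' @export
#' @examples
#' counts <- f2_counts()
#' compare_nested(fit_environmental(counts),
#'                fit_model(counts, spec = hierarchy_specs()$additive))
compare_nested <- function(h0, ha) {
  z0 <- h0$spec$zeroed
  za <- ha$spec$zeroed
  if (!(all(za %in% z0) && length(za) < length(z0))) {
    stop("models are not strictly nested: H0 must zero a proper superset ",
         "of HA's zeroed parameters")
  }
  if (!h0$converged || !ha$converged) stop("both fits must have converged")
  raw <- h0$chisq - ha$chisq
  delta <- raw
  if (raw < 0) {
    warning(sprintf("negative chi-squared difference (%.4g) clamped to 0", raw))
    delta <- 0
  }
  ddf <- h0$df - ha$df
  structure(list(
    h0_name = h0$spec$name, ha_name = ha$spec$name,
    delta_chisq = delta, delta_chisq_raw = raw, delta_df = ddf,
    p_value = stats::pchisq(delta, ddf, lower.tail = FALSE)
  ), class = "nested_comparison")
}

#' @export
print.nested_comparison <- function(x, ...) {
  cat(sprintf("%s (H0) vs %s (HA): delta chisq = %.2f on %d df, P = %.4g\n",
              x$h0_name, x$ha_name, x$delta_chisq, x$delta_df, x$p_value))
  invisible(x)
}

#' Heritability from nested chi-squared statistics
#'
#' Broad-sense heritability estimated as the ratio of additive variation to
#' total variation: `(chisq_environmental - chisq_additive) /
#' chisq_environmental`, where the environmental model's chi-squared
#' measures total variation in the progeny ratios and the additive model's
#' chi-squared the variation left unexplained by additive gene effects.
#'
#' @param chisq_environmental Chi-squared of the no-genetic-effects model
#'   (total variation); must be positive.
#' @param chisq_additive Chi-squared of the additive model.
#' @return List of class `heritability_estimate` with the two inputs and
#'   `h_squared`.
#' @export
#' @examples
#' heritability(84.27, 44.61)$h_squared  # 0.47 to two decimals
heritability <- function(chisq_environmental, chisq_additive) {
  if (!is.finite(chisq_environmental) || chisq_environmental <= 0) {
    stop("chisq_environmental must be positive (total variation is zero: ",
         "heritability is undefined)")
  }
  structure(list(
    chisq_environmental = chisq_environmental,
    chisq_additive = chisq_additive,
    h_squared = (chisq_environmental - chisq_additive) / chisq_environmental
  ), class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("H^2 = (%.2f - %.2f)/%.2f = %.2f\n", x$chisq_environmental,
              x$chisq_additive, x$chisq_environmental, x$h_squared))
  invisible(x)
}

#' Standard errors from the inverse information matrix
#'
#' Square roots of the diagonal of the inverse of the expected information
#' `N X'AX` evaluated at the ML estimates; one entry per free parameter
#' (zeroed parameters get none).
#'
#' @param fit A converged `inheritance_fit`.
#' @return Named numeric vector of standard errors.
#' @export
standard_errors <- function(fit) {
  if (!fit$converged) stop("fit did not converge; standard errors unavailable")
  if (!length(fit$free)) return(stats::setNames(numeric(), character()))
  inv <- tryCatch(solve(fit$information),
                  error = function(e) stop("singular information matrix"))
  stats::setNames(sqrt(diag(inv)), fit$free)
}

#' Fit the full model hierarchy and assemble the report
#'
#' Fits all ten models of the standard hierarchy to a progeny count table,
#' performs the nested comparison each row is paired with, and appends the
#' heritability estimated from the environmental and additive rows.
#'
#' @param counts A `cross_counts` table (or 3 x 3 matrix).
#' @param design A `genetic_design`.
#' @param tol,max_iter Passed to [fit_model()].
#' @return Object of class `hierarchy_report`: a data frame with one row
#'   per model (columns `model`, `chisq`, `df`, `p`, `delta_chisq`,
#'   `delta_df`, `p_vs`, `vs`) plus attributes `heritability`
#'   (a `heritability_estimate` or `NULL` when undefined) and `fits`
#'   (the named list of `inheritance_fit` objects).
#' @export
#' @examples
#' hierarchy_table(f2_counts())
hierarchy_table <- function(counts, design = default_design(),
                            tol = 1e-8, max_iter = 100L) {
  counts <- cross_counts(counts)
  specs <- hierarchy_specs()
  fits <- list()
  rows <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    fit <- tryCatch(fit_model(counts, design, sp, tol = tol, max_iter = max_iter),
                    error = function(e) e)
    fits[[nm]] <- fit
    if (inherits(fit, "error")) {
      rows[[nm]] <- data.frame(model = nm, chisq = NA_real_, df = NA_integer_,
                               p = NA_real_, delta_chisq = NA_real_,
                               delta_df = NA_integer_, p_vs = NA_real_,
                               vs = NA_character_)
      warning("model ", nm, " failed: ", conditionMessage(fit))
      next
    }
    parent <- attr(sp, "compare_to")
    cmp <- NULL
    if (!is.na(parent) && inherits(fits[[parent]], "inheritance_fit")) {
      cmp <- compare_nested(fit, fits[[parent]])
    }
    rows[[nm]] <- data.frame(
      model = nm,
      chisq = fit$chisq,
      df = fit$df,
      p = if (fit$df > 0) stats::pchisq(fit$chisq, fit$df, lower.tail = FALSE) else NA_real_,
      delta_chisq = if (is.null(cmp)) NA_real_ else cmp$delta_chisq,
      delta_df = if (is.null(cmp)) NA_integer_ else cmp$delta_df,
      p_vs = if (is.null(cmp)) NA_real_ else cmp$p_value,
      vs = if (is.null(cmp)) NA_character_ else parent
    )
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  env_fit <- fits[["environmental"]]
  add_fit <- fits[["additive"]]
  h2 <- NULL
  if (inherits(env_fit, "inheritance_fit") && inherits(add_fit, "inheritance_fit") &&
      is.finite(env_fit$chisq) && env_fit$chisq > 0) {
    h2 <- heritability(env_fit$chisq, add_fit$chisq)
  }
  structure(tab, heritability = h2, fits = fits,
            class = c("hierarchy_report", "data.frame"))
}

#' @export
print.hierarchy_report <- function(x, ...) {
  out <- as.data.frame(x)
  out$chisq <- sprintf("%.2f", out$chisq)
  out$p <- ifelse(is.na(out$p), "-", sprintf("%.4g", out$p))
  out$delta_chisq <- ifelse(is.na(out$delta_chisq), "-", sprintf("%.2f", out$delta_chisq))
  out$p_vs <- ifelse(is.na(out$p_vs), "-", sprintf("%.4g", out$p_vs))
  out$vs <- ifelse(is.na(out$vs), "-", out$vs)
  print(out, row.names = FALSE)
  h2 <- attr(x, "heritability")
  if (!is.null(h2)) print(h2) else cat("H^2 undefined (no total variation)\n")
  invisible(x)
}
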