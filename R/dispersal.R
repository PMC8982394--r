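#' Radial distances from colony-center coordinates
#'
#' Euclidean distance from a fixed origin (the membrane center) to each
#' colony center, preserving input order.
#'
#' @param colony_centers Two-column matrix or data frame of (x, y)
#'   coordinates, in cm.
#' @param origin Length-2 numeric, default `c(0, 0)`.
#' @return Numeric vector of distances, cm.
#' @export
#' @examples
#' radial_distances(rbind(c(3, 4), c(0, 1)))  # 5, 1
radial_distances <- function(colony_centers, origin = c(0, 0)) {
  xy <- as.matrix(colony_centers)
  if (ncol(xy) != 2L) stop("colony_centers must have two columns (x, y)")
  if (!all(is.finite(xy)) || !all(is.finite(origin))) {
    stop("coordinates must be finite")
  }
  sqrt((xy[, 1L] - origin[1L])^2 + (xy[, 2L] - origin[2L])^2)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Sup-norm distance between the two empirical distribution functions,
#' evaluated over the pooled sorted values.
#'
#' @param x,y Non-empty numeric vectors (e.g. dispersal distances, cm).
#' @return D in `[0, 1]`.
#' @export
#' @examples
#' ks_statistic(c(1, 3), c(2, 4))  # 0.5
ks_statistic <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  pooled <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(pooled)
  fy <- stats::ecdf(y)(pooled)
  max(abs(fx - fy))
}

# internal: exact null P(D >= d) by lattice-path counting over the
# (n1, n2) grid. Paths are counted in probability units to avoid
# overflowing C(n1+n2, n1): v(i, j) is the probability that a uniformly
# random interleaving reaches (i, j) while |i/n1 - j/n2| stays < d.
ks_exact_pvalue <- function(d, n1, n2) {
  if (d <= 0) return(1)
  # attainable deviations |i*n2 - j*n1| are integers; snap the threshold
  # d*n1*n2 to the nearest integer when it is close (covers both exact
  # lattice D values subject to floating-point error and D reported
  # rounded to ~5 digits), so P(D >= d_observed) includes ties at d
  t <- d * n1 * n2
  md <- (if (abs(t - round(t)) < 0.1) round(t) else ceiling(t)) - 0.5
  v_prev <- numeric(n2 + 1L)
  for (j in 0:n2) {
    v_prev[j + 1L] <- if (abs(j * n1) >= md) 0 else 1  # row i = 0
  }
  for (i in 1:n1) {
    v <- numeric(n2 + 1L)
    v[1L] <- if (abs(i * n2) >= md) 0 else v_prev[1L]  # j = 0 column
    # probability recursion: v(i,j) = v(i-1,j)*i/(i+j) + v(i,j-1)*j/(i+j)
    for (j in seq_len(n2)) {
      if (abs(i * n2 - j * n1) >= md) {
        v[j + 1L] <- 0
      } else {
        v[j + 1L] <- (v_prev[j + 1L] * i + v[j] * j) / (i + j)
      }
    }
    v_prev <- v
  }
  min(1, max(0, 1 - v_prev[n2 + 1L]))
}

# internal: asymptotic Kolmogorov tail Q(lambda) = 2 sum (-1)^(k-1) exp(-2 k^2 lambda^2)
ks_asymptotic_pvalue <- function(d, n1, n2) {
  lambda <- d * sqrt(n1 * n2 / (n1 + n2))
  if (lambda <= 0) return(1)
  total <- 0
  for (k in 1:200) {
    term <- exp(-2 * k^2 * lambda^2)
    total <- total + (-1)^(k - 1) * term
    if (term < 1e-12) break
  }
  min(1, max(0, 2 * total))
}

#' Two-sample Kolmogorov-Smirnov p-value from a D statistic
#'
#' Computes `P(D >= d)` under the null of a common continuous distribution.
#' The exact method counts lattice paths over the `(n1, n2)` grid (valid
#' only without ties); the asymptotic method sums the alternating
#' Kolmogorov series at `lambda = d * sqrt(n1 n2 / (n1 + n2))`, truncated
#' when a term drops below 1e-12 and clamped to `[0, 1]`. `method =
#' "auto"` selects exact when `n1 * n2 < 10000` and no ties are flagged,
#' asymptotic otherwise.
#'
#' @param d Observed KS statistic in `[0, 1]`.
#' @param n1,n2 Sample sizes.
#' @param method `"auto"`, `"exact"`, or `"asymptotic"`.
#' @param ties_present Whether the underlying samples contained ties.
#' @return Object of class `ks_result`: list with `d_statistic`,
#'   `p_value`, `method` (the one actually used), `n1`, `n2`.
#' @export
#' @examples
#' ks_pvalue(0.2109, 195, 104)$p_value   # ~0.0048, asymptotic
#' ks_pvalue(0.24982, 35, 195)$p_value   # ~0.049, exact
ks_pvalue <- function(d, n1, n2, method = c("auto", "exact", "asymptotic"),
                      ties_present = FALSE) {
  method <- match.arg(method)
  if (!is.finite(d) || d < 0 || d > 1) stop("d must lie in [0, 1]")
  if (n1 < 1 || n2 < 1) stop("sample sizes must be >= 1")
  if (method == "auto") {
    if (n1 * n2 < 10000 && !ties_present) {
      method <- "exact"
    } else {
      if (n1 * n2 < 10000 && ties_present) {
        message("ties present: falling back to the asymptotic p-value")
      }
      method <- "asymptotic"
    }
  }
  if (method == "exact" && ties_present) {
    stop("exact p-value is undefined with ties; use method = \"asymptotic\"")
  }
  p <- switch(method,
              exact = ks_exact_pvalue(d, n1, n2),
              asymptotic = ks_asymptotic_pvalue(d, n1, n2))
  structure(list(d_statistic = d, p_value = p, method = method,
                 n1 = as.integer(n1), n2 = as.integer(n2)),
            class = "ks_result")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Composes [ks_statistic()] and [ks_pvalue()], detecting ties in the
#' pooled sample automatically.
#'
#' @param x,y Non-empty numeric vectors.
#' @param method Passed to [ks_pvalue()].
#' @return A `ks_result`.
#' @export
#' @examples
#' set.seed(1)
#' ks_test(rnorm(50), rnorm(50))
ks_test <- function(x, y, method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  d <- ks_statistic(x, y)
  ties <- anyDuplicated(c(x, y)) > 0
  ks_pvalue(d, length(x), length(y), method = method, ties_present = ties)
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS test (%s): D = %.5g, P = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$d_statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' W statistic and p-value by Royston's published approximation (as
#' implemented in the standard AS R94 routine), applied e.g. to a strain's
#' dispersal distances to check the normal-coordinate assumption.
#'
#' @param x Numeric vector, `3 <= n <= 5000`.
#' @return List of class `normality_result`: `w_statistic`, `p_value`, `n`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000 (n = ", n, ")")
  sw <- stats::shapiro.test(x)
  structure(list(w_statistic = unname(sw$statistic),
                 p_value = sw$p.value, n = n),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk: W = %.4f, P = %.4g (n = %d)\n",
              x$w_statistic, x$p_value, x$n))
  invisible(x)
}

#' Standardize a maximum dispersal distance against a reference
#'
#' `z = (max - mean) / sqrt(variance)` and its square. Under a normal
#' dispersal coordinate the standardized distance squared is approximately
#' chi-squared with 1 degree of freedom, which is what the largest-rank
#' tail test consumes.
#'
#' @param max_distance Observed maximum distance, cm.
#' @param reference_mean Reference mean movement (cm).
#' @param reference_variance Reference sample variance (cm^2); must be > 0.
#' @return List with `z` and `z_squared`.
#' @export
#' @examples
#' standardized_max(25.78, 4.729, 2.165)$z_squared  # ~204.7
standardized_max <- function(max_distance, reference_mean, reference_variance) {
  if (!is.finite(reference_variance) || reference_variance <= 0) {
    stop("reference_variance must be positive")
  }
  z <- (max_distance - reference_mean) / sqrt(reference_variance)
  list(z = z, z_squared = z^2)
}

#' Tail probability of the largest of n chi-squared(1) draws
#'
#' `P(max of n_ranks independent chi-squared(1) variables >= z_squared)
#' = 1 - F(z_squared)^n_ranks`, the order-statistic tail used to judge
#' whether an observed maximum dispersal distance is compatible with a
#' reference dispersal distribution. The single-draw tail
#' `1 - F(z_squared)` is also returned.
#'
#' @param z_squared Squared standardized maximum; >= 0.
#' @param n_ranks Number of order statistics treated as draws from the
#'   same distribution (default 3, one per strain maximum).
#' @return List of class `max_dispersal_tail`: `largest_rank_tail`,
#'   `chisq1_tail`, `z_squared`, `n_ranks`.
#' @export
#' @examples
#' largest_rank_tail(3.841, n_ranks = 1)$largest_rank_tail  # ~0.05
largest_rank_tail <- function(z_squared, n_ranks = 3L) {
  if (!is.finite(z_squared) || z_squared < 0) stop("z_squared must be >= 0")
  if (n_ranks < 1) stop("n_ranks must be >= 1")
  # log-scale survival of the maximum: stable when the single-draw tail
  # is tiny and F^n would round to 1
  log_f <- stats::pchisq(z_squared, df = 1, log.p = TRUE)
  tail_max <- -expm1(n_ranks * log_f)
  structure(list(
    largest_rank_tail = min(1, max(0, tail_max)),
    chisq1_tail = stats::pchisq(z_squared, df = 1, lower.tail = FALSE),
    z_squared = z_squared,
    n_ranks = as.integer(n_ranks)
  ), class = "max_dispersal_tail")
}

#' Maximum-dispersal report for one strain against a reference
#'
#' Standardizes the strain's maximum distance against the reference mean
#' and variance and computes both the chi-squared(1) tail and the
#' largest-rank (order-statistic) tail.
#'
#' @param max_distance Maximum distance traveled, cm.
#' @param reference_mean,reference_variance Reference movement mean (cm)
#'   and variance (cm^2).
#' @param n_ranks Number of strain maxima treated as order statistics.
#' @return List of class `max_dispersal_result` combining the z-score and
#'   both tails.
#' @export
#' @examples
#' max_dispersal_test(25.78, 4.729, 2.165)
max_dispersal_test <- function(max_distance, reference_mean,
                               reference_variance, n_ranks = 3L) {
  z <- standardized_max(max_distance, reference_mean, reference_variance)
  tail <- largest_rank_tail(z$z_squared, n_ranks)
  structure(c(list(max_distance = max_distance,
                   reference_mean = reference_mean,
                   reference_variance = reference_variance,
                   z = z$z), unclass(tail)),
            class = "max_dispersal_result")
}

#' @export
print.max_dispersal_result <- function(x, ...) {
  cat(sprintf("Max dispersal %.2f cm vs reference (mean %.3f, var %.3f):\n",
              x$max_distance, x$reference_mean, x$reference_variance))
  cat(sprintf("  z = %.3f, z^2 = %.1f\n", x$z, x$z_squared))
  cat(sprintf("  chi-squared(1) tail = %.3g; largest-rank tail (n = %d) = %.3g\n",
              x$chisq1_tail, x$n_ranks, x$largest_rank_tail))
  invisible(x)
}
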