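test_that("radial distances are Euclidean norms from the origin", {
  expect_equal(radial_distances(rbind(c(0, 0))), 0)
  expect_equal(radial_distances(rbind(c(3, 4))), 5)
  expect_equal(radial_distances(rbind(c(4, 5)), origin = c(1, 1)), 5)
  set.seed(3)
  d <- radial_distances(matrix(rnorm(200), ncol = 2))
  expect_true(all(d >= 0 & is.finite(d)))
  expect_error(radial_distances(rbind(c(1, NA))), "finite")
})

test_that("KS statistic matches enumerated EDF steps and is symmetric", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2), c(3, 4)), 1)
  expect_equal(ks_statistic(c(1, 3), c(2, 4)), 0.5)
  set.seed(5)
  for (r in 1:10) {
    x <- rnorm(20); y <- rnorm(30)
    expect_equal(ks_statistic(x, y), ks_statistic(y, x))
    # invariant to a strictly increasing transform of both samples
    expect_equal(ks_statistic(x, y), ks_statistic(exp(x), exp(y)))
  }
  expect_error(ks_statistic(numeric(), 1), "non-empty")
})

test_that("exact KS p-value equals brute-force interleaving enumeration", {
  sizes <- list(c(1, 1), c(2, 2), c(3, 2), c(3, 3), c(4, 3), c(5, 4),
                c(6, 5), c(6, 6), c(8, 4), c(10, 2), c(7, 5))
  for (s in sizes) {
    n1 <- s[1]; n2 <- s[2]
    # every achievable D value on the (n1, n2) lattice
    ij <- expand.grid(i = 0:n1, j = 0:n2)
    dvals <- sort(unique(abs(ij$i / n1 - ij$j / n2)))
    dvals <- dvals[dvals > 0]
    for (d in dvals) {
      expect_equal(ks_pvalue(d, n1, n2, method = "exact")$p_value,
                   ks_enumeration_pvalue(d, n1, n2),
                   tolerance = 1e-10,
                   label = sprintf("exact p at d=%.4f, n=(%d,%d)", d, n1, n2))
    }
  }
})

test_that("exact KS p-value agrees with the independent reference routine", {
  # psmirnov is never used by the implementation; lattice-exact D values
  # avoid threshold-rounding ambiguity between conventions
  for (s in list(c(5, 7), c(10, 10), c(35, 12))) {
    n1 <- s[1]; n2 <- s[2]
    for (k in 1:5) {
      d <- k / min(n1, n2)
      expect_equal(ks_pvalue(d, n1, n2, method = "exact")$p_value,
                   stats::psmirnov(d, sizes = c(n1, n2), lower.tail = FALSE),
                   tolerance = 1e-9)
    }
  }
})

test_that("asymptotic KS p-value approaches the exact one at n = 100", {
  for (d in seq(0.05, 0.4, by = 0.05)) {
    pe <- ks_pvalue(d, 100, 100, method = "exact")$p_value
    pa <- ks_pvalue(d, 100, 100, method = "asymptotic")$p_value
    expect_lt(abs(pe - pa), 0.005)
  }
})

test_that("KS p-value handles the degenerate ends and the selection rule", {
  expect_equal(ks_pvalue(0, 10, 12)$p_value, 1)
  expect_equal(ks_pvalue(1, 2, 2, method = "exact")$p_value, 1 / 3)
  expect_identical(ks_pvalue(0.2, 35, 195)$method, "exact")      # 6825 < 1e4
  expect_identical(ks_pvalue(0.2, 195, 104)$method, "asymptotic") # 20280
  expect_identical(suppressMessages(
    ks_pvalue(0.2, 35, 195, ties_present = TRUE))$method, "asymptotic")
  expect_error(ks_pvalue(0.2, 5, 5, method = "exact", ties_present = TRUE),
               "ties")
  expect_error(ks_pvalue(1.2, 5, 5), "\\[0, 1\\]")
})

test_that("ks_test composes statistic and p-value with tie detection", {
  x <- c(1, 2, 3, 4)
  r <- ks_test(x, x)
  expect_equal(r$d_statistic, 0)
  expect_equal(r$p_value, 1)
  # disjoint supports at n = 20 each: exact recursion at D = 1
  r2 <- ks_test(1:20, 101:120)
  expect_identical(r2$method, "exact")
  expect_equal(r2$d_statistic, 1)
  expect_lt(r2$p_value, 1e-6)
  # duplicated values force the asymptotic fallback under auto
  r3 <- suppressMessages(ks_test(c(1, 1, 2, 5), c(3, 4, 6, 7)))
  expect_identical(r3$method, "asymptotic")
})

test_that("null KS tests reject at close to the nominal rate", {
  set.seed(101)
  pvals <- replicate(500, ks_test(rnorm(200), rnorm(200))$p_value)
  expect_gte(mean(pvals < 0.05), 0.03)
  expect_lte(mean(pvals < 0.05), 0.07)
})

test_that("Shapiro-Wilk wrapper flags gross non-normality and near-normals", {
  grid <- qnorm(ppoints(50))
  expect_gt(shapiro_wilk(grid)$w_statistic, 0.99)
  spike <- c(rep(1, 19), 100)
  expect_lt(shapiro_wilk(spike)$p_value, 0.01)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  # agreement with the reference implementation on a seeded lognormal sample
  set.seed(77)
  x <- rlnorm(60)
  ours <- shapiro_wilk(x)
  ref <- stats::shapiro.test(x)
  expect_equal(ours$w_statistic, unname(ref$statistic), tolerance = 1e-6)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("standardized maximum reproduces the reference arithmetic", {
  # Wrap and Bulky maxima against the reported movement mean and variance
  expect_equal(standardized_max(25.78, 4.729, 2.165)$z_squared,
               (25.78 - 4.729)^2 / 2.165, tolerance = 1e-12)
  expect_equal(round(standardized_max(25.78, 4.729, 2.165)$z_squared, 1), 204.7)
  expect_equal(round(standardized_max(24.16, 4.729, 2.165)$z_squared, 1), 174.4)
  expect_equal(standardized_max(4.729, 4.729, 2.165)$z, 0)
  expect_error(standardized_max(1, 0, 0), "positive")
})

test_that("largest-rank tail has the order-statistic form and bounds", {
  expect_equal(largest_rank_tail(0, n_ranks = 1)$largest_rank_tail, 1)
  expect_equal(largest_rank_tail(3.841, n_ranks = 1)$largest_rank_tail,
               0.05, tolerance = 1e-3)
  # closed form 1 - F^n against direct computation on a grid
  for (z2 in c(0.5, 2, 10)) {
    for (n in c(1, 3, 10)) {
      expect_equal(largest_rank_tail(z2, n)$largest_rank_tail,
                   1 - pchisq(z2, 1)^n, tolerance = 1e-12)
    }
  }
  # monotone: non-increasing in z^2, non-decreasing in n_ranks
  z2s <- c(0.1, 1, 5, 50, 174.4, 204.7)
  tails <- vapply(z2s, function(z) largest_rank_tail(z, 3)$largest_rank_tail,
                  numeric(1))
  expect_true(all(diff(tails) < 0))
  ns <- 1:6
  tn <- vapply(ns, function(n) largest_rank_tail(2, n)$largest_rank_tail,
               numeric(1))
  expect_true(all(diff(tn) > 0))
  # Bonferroni-style upper bound: <= min(1, n * single-draw tail)
  for (z2 in c(0.2, 3, 30)) {
    for (n in c(2, 5)) {
      r <- largest_rank_tail(z2, n)
      expect_lte(r$largest_rank_tail, min(1, n * r$chisq1_tail) + 1e-12)
    }
  }
  # stays meaningful where naive 1 - F^n underflows to 0
  expect_gt(largest_rank_tail(204.7, 3)$largest_rank_tail, 0)
})

test_that("simulated squared dispersal distances are chi-squared(2)", {
  set.seed(303)
  rejections <- replicate(500, {
    d <- simulate_dispersal(200, sigma = 3)
    suppressWarnings(ks.test(d^2 / 9, "pchisq", df = 2)$p.value) < 0.05
  })
  expect_lte(mean(rejections), 0.07)
})
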