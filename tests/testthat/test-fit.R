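test_that("environmental fit reproduces hand-computed Pearson sums", {
  # symmetric table: nine cells each contributing (obs - 2)^2 / 2
  sym <- rbind(c(4, 1, 1), c(1, 4, 1), c(1, 1, 4))
  fit <- fit_environmental(sym)
  expect_equal(fit$chisq, 9)
  expect_identical(fit$df, 6L)
  expect_identical(fit$iterations, 0L)
  expect_equal(unname(fit$expected_counts), matrix(2, 3, 3))

  # observed equal to expected gives exactly zero
  expect_equal(fit_environmental(matrix(5, 3, 3))$chisq, 0)
})

test_that("environmental chi-squared is independent of the design matrix", {
  counts <- f2_counts_matrix()
  c1 <- fit_model(counts, default_design(),
                  model_spec("environmental", parameter_names()))$chisq
  c2 <- fit_model(counts, flipped_design(),
                  model_spec("environmental", parameter_names()))$chisq
  expect_identical(c1, c2)
})

test_that("pearson_chisq validates its contract", {
  expect_equal(pearson_chisq(matrix(2, 3, 3), matrix(2, 3, 3)), 0)
  expect_error(pearson_chisq(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
  expect_error(pearson_chisq(matrix(1, 3, 3), matrix(0, 3, 3)), "positive")
})

test_that("uniform counts give a zero-effect saturated fit", {
  fit <- fit_model(matrix(50, 3, 3))
  expect_equal(unname(fit$theta_hat), rep(0, 6), tolerance = 1e-10)
  expect_equal(fit$chisq, 0, tolerance = 1e-12)
})

test_that("full six-parameter fit is saturated on attainable tables", {
  fit <- fit_model(f2_counts_matrix())
  expect_true(fit$converged)
  expect_identical(fit$df, 0L)
  expect_lt(fit$chisq, 1e-6)
  expect_equal(unname(fit$fitted_probs),
               unname(f2_counts_matrix() / rowSums(f2_counts_matrix())),
               tolerance = 1e-9)
  set.seed(11)
  for (r in 1:10) {
    tab <- random_cross_table()
    f <- fit_model(tab)
    expect_lt(f$chisq, 1e-6)
    expect_equal(unname(rowSums(f$fitted_probs)), rep(1, 3), tolerance = 1e-9)
  }
})

test_that("forward-model counts recover the generating parameters", {
  theta_star <- c(0.06, -0.03, 0.03, 0.03, -0.03, 0.00)
  p <- model_probabilities(theta_star)
  counts <- round(6000 * p)
  fit <- fit_model(counts)
  expect_lt(max(abs(fit$theta_hat - theta_star)), 0.01)
  # against the derivative-free ML oracle as well
  oracle <- nm_fit_theta(counts)
  expect_lt(max(abs(fit$theta_hat - oracle)), 1e-5)
})

test_that("IRLS matches the derivative-free ML oracle", {
  fit <- fit_model(f2_counts_matrix())
  oracle <- nm_fit_theta(f2_counts_matrix())
  expect_lt(max(abs(fit$theta_hat[parameter_names()] - oracle)), 1e-5)
  set.seed(23)
  for (r in 1:20) {
    tab <- random_cross_table()
    fit <- fit_model(tab)
    oracle <- nm_fit_theta(tab)
    expect_lt(max(abs(fit$theta_hat[parameter_names()] - oracle)), 1e-5)
  }
})

test_that("restricted fits hold zeroed parameters at exactly zero", {
  fit <- fit_model(f2_counts_matrix(), spec = hierarchy_specs()$additive)
  expect_identical(unname(fit$theta_hat[c("alpha_beta", "beta_gamma",
                                          "alpha_gamma")]), rep(0, 3))
  expect_identical(fit$df, 3L)
  expect_setequal(fit$free, c("alpha", "beta", "gamma"))
  # the restricted optimum also agrees with the oracle on the free subset
  oracle <- nm_fit_theta(f2_counts_matrix(), free = fit$free)
  expect_lt(max(abs(fit$theta_hat[fit$free] - oracle)), 1e-5)
})

test_that("standard errors scale as 1/sqrt(2) when counts double", {
  counts <- f2_counts_matrix()
  se1 <- standard_errors(fit_model(counts))
  se2 <- standard_errors(fit_model(2 * counts))
  expect_true(all(se1 > 0 & is.finite(se1)))
  expect_equal(unname(se2), unname(se1 / sqrt(2)), tolerance = 1e-9)
})

test_that("information-matrix standard errors match the parametric bootstrap", {
  fit <- fit_model(f2_counts_matrix())
  n_i <- rowSums(f2_counts_matrix())
  set.seed(42)
  boots <- replicate(2000, {
    tab <- t(vapply(1:3, function(i) {
      as.integer(rmultinom(1, n_i[i], fit$fitted_probs[i, ]))
    }, integer(3)))
    fit_model(tab)$theta_hat
  })
  boot_sd <- apply(boots, 1, sd)[parameter_names()]
  expect_equal(unname(standard_errors(fit)), unname(boot_sd),
               tolerance = 0.02)
})

test_that("nested comparisons follow the chi-squared-difference rules", {
  counts <- f2_counts_matrix()
  env <- fit_environmental(counts)
  add <- fit_model(counts, spec = hierarchy_specs()$additive)
  cmp <- compare_nested(env, add)
  expect_equal(cmp$delta_chisq, env$chisq - add$chisq)
  expect_identical(cmp$delta_df, 3L)
  expect_equal(cmp$p_value,
               pchisq(cmp$delta_chisq, 3, lower.tail = FALSE))

  # identical fits: zero difference, p = 1 (via two nested specs that both
  # attain the same optimum on uniform data)
  uni <- matrix(40, 3, 3)
  cmp0 <- suppressWarnings(  # a ~1e-30 negative difference may be clamped
    compare_nested(fit_model(uni, spec = hierarchy_specs()$ab_zero),
                   fit_model(uni)))
  expect_equal(cmp0$delta_chisq, 0, tolerance = 1e-10)
  expect_equal(cmp0$p_value, 1, tolerance = 1e-6)

  # the single-df comparison arithmetic: delta chisq 13.37 on 1 df
  expect_equal(pchisq(13.37, 1, lower.tail = FALSE), 2.557e-4,
               tolerance = 1e-3)

  # non-nested pairs refuse
  expect_error(compare_nested(fit_model(counts, spec = hierarchy_specs()$ab_zero),
                              fit_model(counts, spec = hierarchy_specs()$bg_zero)),
               "not strictly nested")
})

test_that("heritability is the additive-to-total variation ratio", {
  h <- heritability(84.27, 44.61)
  expect_equal(round(h$h_squared, 2), 0.47)
  expect_equal(heritability(10, 10)$h_squared, 0)
  expect_equal(heritability(10, 0)$h_squared, 1)
  expect_error(heritability(0, 0), "positive")
})

test_that("hierarchy table has the documented df ladder and monotone nesting", {
  report <- hierarchy_table(f2_counts_matrix())
  expect_identical(report$df, c(0L, 1L, 2L, 1L, 2L, 2L, 1L, 2L, 3L, 6L))
  expect_equal(report$chisq[report$model == "environmental"], 84.27,
               tolerance = 1e-4)
  expect_lt(report$chisq[report$model == "full_epistatic"], 1e-6)
  # every child fits no better than its parent
  for (i in seq_len(nrow(report))) {
    parent <- report$vs[i]
    if (is.na(parent)) next
    expect_gte(report$chisq[i],
               report$chisq[report$model == parent] - 1e-6)
  }
  h2 <- attr(report, "heritability")
  expect_s3_class(h2, "heritability_estimate")
  expect_true(h2$h_squared > 0 && h2$h_squared < 1)
})

test_that("hierarchy on uniform counts is degenerate but guarded", {
  report <- hierarchy_table(matrix(30, 3, 3))
  expect_true(all(report$chisq < 1e-8))
  expect_null(attr(report, "heritability"))
})

test_that("count table validation catches contract violations", {
  expect_error(cross_counts(matrix(1, 2, 2)), "3 x 3")
  expect_error(cross_counts(matrix(-1, 3, 3)), "non-negative")
  expect_error(cross_counts(matrix(c(0, 0, 0, rep(5, 6)), 3, 3, byrow = TRUE)),
               "at least one progeny")
  expect_error(cross_counts(matrix(1.5, 3, 3)), "whole numbers")
})

test_that("collinear free columns raise a clear error", {
  d <- default_design()
  broken <- lapply(d$matrices, function(m) { m[, 2] <- m[, 1]; m })
  expect_error(fit_model(f2_counts_matrix(), default_design(broken)),
               "collinear")
})
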