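test_that("t_optimal is the vertex of the fitted quadratic", {
  fit <- fake_quadratic_fit(c(-10, 1.2, -0.04))
  expect_equal(t_optimal(fit), 15)
  expect_error(t_optimal(fake_quadratic_fit(c(-10, 1.2, 0.01))),
               "unimodal")
})

test_that("t_optimal is equivariant under temperature shifts and label rescaling", {
  truth <- coeffs_from_shape(15.6, 0.7, 4.7)
  d <- simulate_lab(truth, n_per_temp = 30, seed = 17)
  fit <- fit_tpc(d, tpc_model_spec())
  d_shift <- dplyr::mutate(d, temperature = temperature + 3)
  fit_shift <- fit_tpc(d_shift, tpc_model_spec())
  expect_equal(t_optimal(fit_shift), t_optimal(fit) + 3, tolerance = 1e-4)

  # swapping success/failure labels flips the curve but keeps the vertex
  d_flip <- dplyr::mutate(d, outcome = 1L - outcome)
  fit_flip <- fit_tpc(d_flip, tpc_model_spec())
  expect_equal(-unname(fit_flip$coefficients),
               unname(fit$coefficients), tolerance = 1e-6)
})

test_that("lr_test matches the chi-squared upper tail and handles edge cases", {
  truth <- coeffs_from_shape(15.6, 0.7, 4.7)
  d <- simulate_lab(truth, n_per_temp = 25, seed = 19)
  full <- fit_tpc(d, tpc_model_spec())
  reduced <- fit_tpc(d, tpc_model_spec(degree = 0))
  lrt <- lr_test(full, reduced)
  expect_equal(lrt$df, 2)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$p_value,
               pchisq(lrt$statistic, 2, lower.tail = FALSE))
  expect_equal(lrt, temperature_lrt(d))

  # identical models: statistic 0, p = 1
  self <- lr_test(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  # a chi-squared of 26.29 on 2 df is significant far below 0.001
  big <- full
  big$loglik <- reduced$loglik + 26.29 / 2
  expect_lt(lr_test(big, reduced)$p_value, 0.001)

  # non-nested specs are a usage error
  lin <- fit_tpc(d, tpc_model_spec(degree = 1))
  gauss_spec <- tpc_model_spec(response = "temperature", degree = 0,
                               family = "gaussian")
  expect_error(lr_test(full, fit_tpc(dplyr::mutate(d, temperature), gauss_spec)),
               "nested")
  expect_identical(lr_test(full, lin)$df, 1L)
})

test_that("the LRT statistic is invariant to centering temperature", {
  truth <- coeffs_from_shape(15.6, 0.7, 4.7)
  d <- simulate_lab(truth, n_per_temp = 25, seed = 23)
  stat1 <- temperature_lrt(d)$statistic
  stat2 <- temperature_lrt(dplyr::mutate(d, temperature = temperature - 15))$statistic
  expect_equal(stat1, stat2, tolerance = 1e-6)
})

test_that("the confidence band is symmetric around the fitted curve", {
  truth <- coeffs_from_shape(15.6, 0.7, 4.7)
  fit <- fit_tpc(simulate_lab(truth, n_per_temp = 25, seed = 29),
                 tpc_model_spec())
  band <- predict_tpc(fit, seq(5, 25, by = 0.5))
  expect_true(all(band$lo <= band$p_hat & band$p_hat <= band$hi))
  expect_equal(band$p_hat - band$lo, band$hi - band$p_hat, tolerance = 1e-12)
})

test_that("tpc_breadth matches a dense scan of the delta-method band", {
  grid <- seq(-10, 40, by = 0.05)
  dense <- seq(-10, 40, by = 0.001)

  # cov = 0.5 I: at these temperatures the band is hopelessly wide; both the
  # bisection rule and a brute-force scan must agree the interval is empty
  vague <- fake_quadratic_fit(c(-10, 1.2, -0.04), vcov = 0.5 * diag(3))
  expect_length(which(predict_tpc(vague, dense)$lo > 0), 0)
  expect_warning(br_empty <- tpc_breadth(vague, grid = grid), "empty")
  expect_equal(br_empty$breadth, 0)
  expect_equal(br_empty$t_optimal, 15)

  # a covariance small enough for a positive band: boundaries match the scan
  fit <- fake_quadratic_fit(c(-10, 1.2, -0.04), vcov = 1e-6 * diag(3))
  br <- tpc_breadth(fit, grid = grid)
  lo <- predict_tpc(fit, dense)$lo
  pos <- which(lo > 0)
  expect_gt(length(pos), 0)
  expect_equal(br$breadth_lo, dense[min(pos)], tolerance = 0.011)
  expect_equal(br$breadth_hi, dense[max(pos)], tolerance = 0.011)
  expect_equal(br$t_optimal, 15)

  # widening alpha never shrinks the interval
  br20 <- tpc_breadth(fit, grid = grid, alpha = 0.20)
  expect_gte(br20$breadth, br$breadth)

  # vanishing coefficient uncertainty: the band's lower limit is the fitted
  # curve, positive everywhere, so breadth fills the grid
  exact_fit <- fake_quadratic_fit(c(-10, 1.2, -0.04), vcov = diag(1e-18, 3))
  br0 <- tpc_breadth(exact_fit, grid = grid)
  expect_equal(c(br0$breadth_lo, br0$breadth_hi), c(-10, 40))
})

test_that("compare_tpcs tests the treatment-by-temperature interaction", {
  t1 <- coeffs_from_shape(15.6, 0.7, 4.7)
  t2 <- coeffs_from_shape(13.1, 0.6, 4.7)
  design <- field_design(n_sites = 25, replicates_per_site = 4, years = 2013,
                         sigma_plot = 0, sigma_year = 0)
  spec <- tpc_model_spec(treatment = "competition", interaction = TRUE)

  d <- simulate_field(design, list(absent = t1, present = t2), seed = 31)
  res <- compare_tpcs(d, spec)
  expect_equal(res$df, 2)

  # one-level treatment is a spec error
  d1 <- simulate_field(design, list(absent = t1), seed = 31)
  expect_error(compare_tpcs(d1, spec), "2 levels")

  # power: a 1.5 deg C optimum shift at 400 trials per arm is usually detected
  shifted <- coeffs_from_shape(14.1, 0.7, 4.7)
  big_design <- field_design(n_sites = 25, replicates_per_site = 16,
                             years = 2013, sigma_plot = 0, sigma_year = 0)
  withr::with_seed(37, {
    rejections <- sum(vapply(1:20, function(i) {
      di <- simulate_field(big_design, list(absent = t1, present = shifted),
                           seed = sample.int(1e6, 1))
      compare_tpcs(di, spec)$p_value < 0.05
    }, logical(1)))
  })
  expect_gt(rejections / 20, 0.5)
})
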