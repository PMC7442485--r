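test_that("the logistic MLE matches a brute-force grid-search oracle", {
  d <- tibble::tibble(temperature = c(10, 12, 14, 16, 18, 20, 16, 12, 20, 14),
                      outcome = c(0, 0, 1, 1, 1, 0, 0, 1, 0, 1))
  fit <- fit_binomial_glm(d)

  steps <- c(1, 0.1, 0.005)
  g <- expand.grid(b0 = seq(-80, 0, by = steps[1]),
                   b1 = seq(0, 12, by = steps[2]),
                   b2 = seq(-0.5, 0, by = steps[3]))
  ll <- rep(0, nrow(g))
  for (i in seq_len(nrow(d))) {
    eta <- g$b0 + g$b1 * d$temperature[i] + g$b2 * d$temperature[i]^2
    ll <- ll + d$outcome[i] * eta - log1p(exp(eta))
  }
  best <- unlist(g[which.max(ll), ])

  expect_gte(fit$loglik, max(ll) - 1e-9)            # the fit dominates the grid
  expect_true(all(abs(unname(fit$coefficients) - best) <= steps))
  expect_equal(fit$loglik,
               bernoulli_loglik(unname(fit$coefficients), d$temperature,
                                d$outcome),
               tolerance = 1e-8)
})

test_that("degenerate and separated data are refused with clear errors", {
  all_ones <- tibble::tibble(temperature = c(10, 14, 18), outcome = c(1, 1, 1))
  expect_error(fit_binomial_glm(all_ones), "Degenerate")

  # successes exactly on {14,16,18}: perfectly separated by a quadratic
  sep <- tibble::tibble(temperature = c(10, 12, 14, 16, 18, 20),
                        outcome = c(0, 0, 1, 1, 1, 0))
  expect_error(fit_binomial_glm(sep), "[Ss]eparation")
})

test_that("GLM recovers simulated coefficients within 3 standard errors", {
  truth <- true_tpc_params(beta0 = -10, beta1 = 1.2, beta2 = -0.04)
  withr::with_seed(51, {
    temperature <- runif(5000, 2, 28)
    p <- plogis(truth$beta0 + truth$beta1 * temperature +
                  truth$beta2 * temperature^2)
    d <- tibble::tibble(temperature = temperature,
                        outcome = rbinom(5000, 1, p))
  })
  fit <- fit_binomial_glm(d)
  se <- sqrt(diag(fit$vcov))
  z <- abs(fit$coefficients - c(truth$beta0, truth$beta1, truth$beta2)) / se
  expect_true(all(z < 3))
})

test_that("records with missing outcomes are dropped with a count", {
  truth <- coeffs_from_shape(15.6, 0.7, 4.7)
  d <- simulate_lab(truth, n_per_temp = 20, seed = 5, dropout_rate = 0.1)
  expect_message(fit <- fit_tpc(d, tpc_model_spec()), "Dropped")
  expect_equal(fit$n + fit$n_dropped, nrow(d))
  expect_equal(fit$n_dropped, sum(is.na(d$outcome)))
})

test_that("GLMM reduces to the GLM when the random-effect variance is zero", {
  truth <- coeffs_from_shape(15.6, 0.7, 4.7)
  design <- field_design(n_sites = 30, replicates_per_site = 4,
                         years = 2013:2014, sigma_plot = 0, sigma_year = 0)
  d <- simulate_field(design, list(absent = truth), seed = 9)
  glmm <- fit_binomial_glmm(d, tpc_model_spec(random = "plot_id"))
  glm_fit <- fit_binomial_glm(d)
  expect_lt(glmm$re_variances[["plot_id"]], 0.05)
  se <- sqrt(diag(glm_fit$vcov))
  expect_true(all(abs(glmm$coefficients - glm_fit$coefficients) < 3 * se))
})

test_that("Laplace marginal likelihood is close to exact integration on a small toy", {
  truth <- coeffs_from_shape(15, 0.6, 5)
  design <- field_design(n_sites = 2, elevations = c(1700, 2400),
                         replicates_per_site = 25, years = 2013,
                         sigma_plot = 1.5, sigma_year = 0, temp_jitter_sd = 3)
  d <- simulate_field(design, list(absent = truth), seed = 104)
  fit <- fit_binomial_glmm(d, tpc_model_spec(random = "plot_id"))
  exact <- exact_glmm_loglik(unname(fit$coefficients),
                             sigma = sqrt(fit$re_variances[["plot_id"]]),
                             data = fit$data)
  expect_lt(abs(fit$loglik - exact), 0.1)
})

test_that("a single-level random factor is a spec error", {
  truth <- coeffs_from_shape(15.6, 0.7, 4.7)
  d <- simulate_lab(truth, n_per_temp = 10, seed = 3)  # plot_id is one level
  expect_error(fit_binomial_glmm(d, tpc_model_spec(random = "plot_id")),
               "singular")
})

test_that("Gaussian fits are exact least squares", {
  # response exactly linear in temperature: residuals vanish
  d <- tibble::tibble(temperature = c(12, 16, 20, 24),
                      response_value = 2 + 0.5 * c(12, 16, 20, 24))
  spec <- tpc_model_spec(response = "response_value", degree = 1,
                         family = "gaussian")
  fit <- suppressWarnings(fit_gaussian_lm(d, spec))  # perfect fit warns in summary.lm
  expect_equal(unname(fit$coefficients), c(2, 0.5), tolerance = 1e-10)

  # group means recovered as intercept + contrasts
  withr::with_seed(61, {
    d2 <- tibble::tibble(
      temperature = rep(c(12, 16, 20), each = 10),
      arm = rep(c("a", "b", "c"), each = 10),
      response_value = rnorm(30, rep(c(1, 3, 2), each = 10), 0.5)
    )
  })
  spec2 <- tpc_model_spec(response = "response_value", degree = 0,
                          treatment = "arm", family = "gaussian")
  fit2 <- fit_gaussian_lm(d2, spec2)
  means <- tapply(d2$response_value, d2$arm, mean)
  expect_equal(unname(fit2$coefficients[1]), unname(means["a"]))
  expect_equal(unname(fit2$coefficients[1] + fit2$coefficients[2]),
               unname(means["b"]))

  # fewer observations than coefficients: rank deficiency
  tiny <- tibble::tibble(temperature = c(12, 14),
                         response_value = c(1, 2))
  expect_error(fit_gaussian_lm(tiny, tpc_model_spec(response = "response_value",
                                                    family = "gaussian")),
               "Collinearity")
})

test_that("tidy() and glance() summarise fits in broom style", {
  truth <- coeffs_from_shape(15.6, 0.7, 4.7)
  fit <- fit_tpc(simulate_lab(truth, n_per_temp = 25, seed = 8),
                 tpc_model_spec())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_equal(gl$n, fit$n)
  expect_true(gl$converged)
})
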