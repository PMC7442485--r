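test_that("coeffs_from_shape produces the stated coefficients and round-trips", {
  p <- coeffs_from_shape(t_opt = 15, p_max = 0.8, h = 5)
  b <- (qlogis(0.8) - qlogis(0.4)) / 25
  expect_equal(p$beta2, -b, tolerance = 1e-10)
  expect_equal(p$beta2, -0.07167, tolerance = 1e-4)
  expect_equal(p$beta1, 2.1500, tolerance = 1e-3)
  expect_equal(p$t_optimal, 15)
  expect_equal(p$p_max, 0.8)

  withr::with_seed(67, {
    for (i in 1:10) {
      t_opt <- runif(1, 5, 25)
      p_max <- runif(1, 0.2, 0.9)
      h <- runif(1, 2, 8)
      tr <- coeffs_from_shape(t_opt, p_max, h)
      expect_equal(tr$t_optimal, t_opt, tolerance = 1e-9)
      # success probability halves at t_opt +/- h by construction
      p_at_h <- plogis(tr$beta0 + tr$beta1 * (t_opt + h) +
                         tr$beta2 * (t_opt + h)^2)
      expect_equal(p_at_h, p_max / 2, tolerance = 1e-9)
    }
  })
  expect_error(coeffs_from_shape(15, 1.2, 5), "p_max")
  expect_error(true_tpc_params(0, 1, 0.1), "beta2")
})

test_that("the lab generator is seed-deterministic and concentrates correctly", {
  truth <- coeffs_from_shape(15.6, 0.7, 4.7)
  a <- simulate_lab(truth, n_per_temp = 15, seed = 71)
  b <- simulate_lab(truth, n_per_temp = 15, seed = 71)
  expect_identical(a, b)
  expect_equal(nrow(a), 6 * 15)
  expect_setequal(unique(a$temperature), c(8, 10, 12, 16, 20, 22))

  big <- simulate_lab(truth, temps = truth$t_optimal, n_per_temp = 10000,
                      seed = 73)
  p <- truth$p_max
  expect_lt(abs(mean(big$outcome) - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("the field generator obeys the design arithmetic and its reductions", {
  truth <- coeffs_from_shape(15.6, 0.7, 4.7)
  design <- field_design(n_sites = 10, replicates_per_site = 3,
                         years = 2013:2015)
  d <- simulate_field(design, list(absent = truth, present = truth), seed = 79)
  expect_equal(nrow(d), 10 * 3 * 3 * 2)
  expect_equal(dplyr::n_distinct(d$plot_id), 10)
  expect_equal(dplyr::n_distinct(d$year), 3)
  expect_setequal(unique(d$competition), c("absent", "present"))
  expect_identical(d, simulate_field(design, list(absent = truth, present = truth),
                                     seed = 79))
  expect_error(simulate_field(design, list(truth), seed = 1), "named")

  # with no random effects and no temperature jitter the field generator is
  # distributionally the lab generator at the site temperatures
  temps <- c(8, 12, 16, 20)
  d0 <- simulate_field(
    field_design(n_sites = 4, elevations = c(1600, 1700, 1800, 1900),
                 base_temp = 8, lapse_rate = 4 / 100,
                 replicates_per_site = 25000, years = 2013,
                 sigma_plot = 0, sigma_year = 0, temp_jitter_sd = 0),
    list(absent = truth), seed = 83
  )
  expect_setequal(unique(d0$temperature), temps)
  rate <- tapply(d0$outcome, d0$temperature, mean)
  p_true <- plogis(truth$beta0 + truth$beta1 * temps + truth$beta2 * temps^2)
  expect_true(all(abs(rate - p_true) < 3 * sqrt(p_true * (1 - p_true) / 25000)))
})

test_that("site temperatures follow the elevational lapse", {
  design <- field_design(n_sites = 3, elevations = c(1600, 2200, 2800))
  expect_equal(design$site_temperatures, c(20, 20 - 0.55 * 6, 20 - 0.55 * 12))
})

test_that("the mechanistic contest rule behaves as the theory dictates", {
  cfg <- default_competitors()
  g <- seq(6, 26, by = 0.05)

  p1 <- competition_success_prob(g, cfg$specialist, cfg$generalist,
                                 cfg$variance_v, group_boost = 1)
  p5 <- competition_success_prob(g, cfg$specialist, cfg$generalist,
                                 cfg$variance_v, group_boost = 5)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # equal weighted performance and no boost: an even contest
  p_self <- competition_success_prob(14, cfg$specialist, cfg$specialist,
                                     cfg$variance_v)
  expect_equal(p_self, 0.5, tolerance = 1e-12)
  # cooperation helps pointwise, and overwhelmingly so in the limit
  expect_true(all(p5 >= p1))
  p_huge <- competition_success_prob(14, cfg$specialist, cfg$generalist,
                                     cfg$variance_v, group_boost = 1e9)
  expect_gt(p_huge, 1 - 1e-6)
  # cooperative groups keep winning (p >= 0.5) into warmer environments
  warm_edge <- function(p) max(g[p >= 0.5])
  expect_gt(warm_edge(p5), warm_edge(p1))
  # the success curve is unimodal for the documented default pair
  peak <- which.max(p1)
  expect_true(all(diff(p1[seq_len(peak)]) >= -1e-9))
  expect_true(all(diff(p1[peak:length(p1)]) <= 1e-9))

  # out-of-range contests warn and fail
  expect_warning(
    p_dead <- competition_success_prob(80, cfg$specialist, cfg$generalist, 1),
    "0"
  )
  expect_equal(p_dead, 0)

  out <- simulate_competition_outcome(g, cfg$specialist, cfg$generalist,
                                      cfg$variance_v, group_boost = 2, seed = 89)
  expect_identical(out, simulate_competition_outcome(
    g, cfg$specialist, cfg$generalist, cfg$variance_v, group_boost = 2,
    seed = 89))
  expect_true(all(out %in% c(0L, 1L)))
})
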