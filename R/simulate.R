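#' Logit-quadratic ground-truth TPC parameters from interpretable shape
#'
#' The synthetic generators draw binary breeding success from a
#' logistic-quadratic TPC, \eqn{\mathrm{logit}\, p(T) = a - b (T - T_{opt})^2}
#' with \eqn{a = \mathrm{logit}(p_{max})} and curvature set so that success
#' probability falls to \eqn{p_{max}/2} at `t_opt +/- h`. In the usual
#' polynomial coordinates \eqn{\beta_2 = -b}, \eqn{\beta_1 = 2 b\, t_{opt}},
#' \eqn{\beta_0 = a - b\, t_{opt}^2}, so `t_optimal()` round-trips to `t_opt`.
#'
#' @param t_opt True optimal temperature, deg C.
#' @param p_max Success probability at the optimum, in (0, 1).
#' @param h Half-probability halfwidth, deg C: the distance from the optimum
#'   at which success probability halves.
#' @return An object of class `true_tpc_params` with elements `beta0`,
#'   `beta1`, `beta2`, `t_optimal`, `p_max`, `h`.
#' @examples
#' coeffs_from_shape(t_opt = 15, p_max = 0.8, h = 5)
#' @export
coeffs_from_shape <- function(t_opt, p_max, h) {
  stopifnot(is.numeric(t_opt), length(t_opt) == 1)
  if (!(p_max > 0 && p_max < 1)) abort("`p_max` must lie in (0, 1).")
  if (!(h > 0)) abort("`h` must be a positive halfwidth (deg C).")
  a <- qlogis(p_max)
  b <- (a - qlogis(p_max / 2)) / h^2
  true_tpc_params(beta0 = a - b * t_opt^2, beta1 = 2 * b * t_opt, beta2 = -b)
}

#' @rdname coeffs_from_shape
#' @param beta0,beta1,beta2 Logit-scale polynomial coefficients; `beta2` must
#'   be negative (unimodal curve).
#' @export
true_tpc_params <- function(beta0, beta1, beta2) {
  if (!(beta2 < 0)) abort("`beta2` must be negative: the true TPC is unimodal.")
  t_opt <- -beta1 / (2 * beta2)
  structure(
    list(beta0 = beta0, beta1 = beta1, beta2 = beta2,
         t_optimal = t_opt,
         p_max = plogis(beta0 + beta1 * t_opt + beta2 * t_opt^2)),
    class = "true_tpc_params"
  )
}

#' @export
print.true_tpc_params <- function(x, ...) {
  cat(sprintf(
    "<true_tpc_params> beta = (%.5f, %.5f, %.5f); t_optimal = %.3f, p_max = %.3f\n",
    x$beta0, x$beta1, x$beta2, x$t_optimal, x$p_max))
  invisible(x)
}

true_success_prob <- function(truth, temperature) {
  plogis(truth$beta0 + truth$beta1 * temperature + truth$beta2 * temperature^2)
}

new_trial_records <- function(temperature, outcome, plot_id, year,
                              competition = "none", group_size = "none",
                              elevation = NA_real_,
                              response_value = NA_real_) {
  tibble(
    temperature = temperature,
    outcome = as.integer(outcome),
    plot_id = as.character(plot_id),
    year = as.character(year),
    competition = as.character(competition),
    group_size = as.character(group_size),
    elevation = elevation,
    response_value = response_value
  )
}

apply_dropout <- function(records, dropout_rate) {
  if (dropout_rate > 0) {
    gone <- stats::runif(nrow(records)) < dropout_rate
    records$outcome[gone] <- NA_integer_
  }
  records
}

#' Simulate a common-garden breeding experiment
#'
#' Emulates a lab design with solitary pairs bred at fixed chamber
#' temperatures (default 8, 10, 12, 16, 20, 22 deg C): each trial succeeds
#' independently with the logistic-quadratic probability implied by `truth`.
#' All trials share a single lab plot/year level, so the records fit with a
#' plain GLM. Deterministic given `seed`.
#'
#' @param truth A [true_tpc_params()] / [coeffs_from_shape()] object.
#' @param temps Chamber temperatures, deg C.
#' @param n_per_temp Trials per temperature.
#' @param seed Integer seed.
#' @param dropout_rate Probability a trial's outcome is lost (e.g. a beetle
#'   death); lost outcomes are recorded as `NA` and dropped before fitting.
#' @return A tibble of trial records.
#' @export
simulate_lab <- function(truth, temps = c(8, 10, 12, 16, 20, 22),
                         n_per_temp = 20, seed, dropout_rate = 0) {
  stopifnot(inherits(truth, "true_tpc_params"), n_per_temp >= 1)
  if (missing(seed)) abort("`seed` is required: generators are pure functions of (config, seed).")
  withr::with_seed(seed, {
    temperature <- rep(temps, each = n_per_temp)
    p <- true_success_prob(truth, temperature)
    rec <- new_trial_records(
      temperature = temperature,
      outcome = rbinom(length(temperature), 1, p),
      plot_id = "lab", year = "lab"
    )
    apply_dropout(rec, dropout_rate)
  })
}

#' Describe an elevational field design
#'
#' Captures the design of the field experiments: sites along an elevational
#' gradient with temperatures set by a linear lapse rate, several replicate
#' trials per site and year, and logit-scale random intercepts for plot and
#' year. Per-trial temperatures add Gaussian day-to-day variation around the
#' site mean, as trials run on different days.
#'
#' @param n_sites Number of study sites (>= 2 for mixed fits).
#' @param elevations Site elevations, m; default evenly spaced 1600-2800 m.
#' @param base_temp Mean temperature at the lowest elevation, deg C.
#' @param lapse_rate Temperature change per metre of elevation (deg C/m);
#'   default -0.55 deg C per 100 m.
#' @param replicates_per_site Replicate trials per site, year and arm.
#' @param years Year labels.
#' @param sigma_plot,sigma_year Random-intercept SDs on the logit scale.
#' @param temp_jitter_sd SD of per-trial temperature variation around the
#'   site mean, deg C.
#' @return An object of class `field_design`.
#' @export
field_design <- function(n_sites = 37,
                         elevations = seq(1600, 2800, length.out = n_sites),
                         base_temp = 20, lapse_rate = -0.55 / 100,
                         replicates_per_site = 3, years = 2013:2016,
                         sigma_plot = 0.5, sigma_year = 0.3,
                         temp_jitter_sd = 1.5) {
  if (n_sites < 2) abort("`n_sites` must be >= 2 (mixed models need >= 2 plots).")
  if (sigma_plot < 0 || sigma_year < 0) abort("Random-intercept SDs must be >= 0.")
  stopifnot(length(elevations) == n_sites, replicates_per_site >= 1)
  structure(
    list(n_sites = n_sites, elevations = elevations,
         site_temperatures = base_temp + lapse_rate * (elevations - elevations[1]),
         replicates_per_site = replicates_per_site, years = years,
         sigma_plot = sigma_plot, sigma_year = sigma_year,
         temp_jitter_sd = temp_jitter_sd),
    class = "field_design"
  )
}

#' Simulate an elevational field experiment
#'
#' For each site x year x treatment arm x replicate, draws a per-trial
#' temperature around the site mean, adds the site's and year's random
#' intercepts (drawn once per level from their design SDs) to the arm's
#' logistic-quadratic TPC, and draws a Bernoulli outcome. Treatment effects
#' are encoded as separate ground-truth TPCs per arm, so both shifts and
#' narrowing of the curve are expressible. Deterministic given `seed`; the
#' record count is `n_sites * replicates_per_site * length(years) * n_arms`.
#'
#' @param design A [field_design()].
#' @param truth_by_arm Named list of [true_tpc_params()], one per treatment
#'   arm (e.g. `list(present = ..., absent = ...)`).
#' @param treatment_var Which treatment column the arm labels populate:
#'   `"competition"` or `"group_size"`.
#' @param seed Integer seed.
#' @param dropout_rate Probability an outcome is lost (recorded as `NA`).
#' @return A tibble of trial records.
#' @export
simulate_field <- function(design, truth_by_arm, treatment_var = c("competition", "group_size"),
                           seed, dropout_rate = 0) {
  stopifnot(inherits(design, "field_design"))
  treatment_var <- match.arg(treatment_var)
  if (missing(seed)) abort("`seed` is required: generators are pure functions of (config, seed).")
  if (is.null(names(truth_by_arm)) || any(names(truth_by_arm) == "")) {
    abort("`truth_by_arm` must be a named list: one `true_tpc_params` per arm.")
  }
  for (arm in names(truth_by_arm)) {
    if (!inherits(truth_by_arm[[arm]], "true_tpc_params")) {
      abort(sprintf("Missing or invalid ground truth for arm `%s`.", arm))
    }
  }

  withr::with_seed(seed, {
    sites <- sprintf("S%02d", seq_len(design$n_sites))
    years <- as.character(design$years)
    u_plot <- setNames(rnorm(length(sites), 0, design$sigma_plot), sites)
    u_year <- setNames(rnorm(length(years), 0, design$sigma_year), years)

    layout <- tidyr::expand_grid(
      site_idx = seq_len(design$n_sites),
      year = years,
      arm = names(truth_by_arm),
      rep = seq_len(design$replicates_per_site)
    )
    temperature <- design$site_temperatures[layout$site_idx] +
      rnorm(nrow(layout), 0, design$temp_jitter_sd)
    b0 <- vapply(truth_by_arm, `[[`, numeric(1), "beta0")[layout$arm]
    b1 <- vapply(truth_by_arm, `[[`, numeric(1), "beta1")[layout$arm]
    b2 <- vapply(truth_by_arm, `[[`, numeric(1), "beta2")[layout$arm]
    eta <- b0 + b1 * temperature + b2 * temperature^2 +
      u_plot[sites[layout$site_idx]] + u_year[layout$year]

    rec <- new_trial_records(
      temperature = temperature,
      outcome = rbinom(nrow(layout), 1, plogis(eta)),
      plot_id = sites[layout$site_idx],
      year = layout$year,
      elevation = design$elevations[layout$site_idx]
    )
    rec[[treatment_var]] <- layout$arm
    apply_dropout(rec, dropout_rate)
  })
}

#' Default theoretical competitor pair
#'
#' The documented specialist/generalist configuration used throughout the
#' examples and the mechanistic generator: a cool thermal specialist
#' (resembling the burying beetle) and a warm, broad generalist (resembling
#' the blowfly), in an environment with temperature variance 4 deg C^2.
#'
#' @return A list with elements `specialist`, `generalist`, `variance_v`.
#' @export
default_competitors <- function() {
  list(
    specialist = fundamental_tpc(t_opt = 16, t_max = 26, sigma_p = 4,
                                 label = "specialist"),
    generalist = fundamental_tpc(t_opt = 23, t_max = 35, sigma_p = 9,
                                 label = "generalist"),
    variance_v = 4
  )
}

#' Success probability under the mechanistic two-species contest
#'
#' A beetle pair (or group) wins the carcass with probability proportional to
#' its temperature-weighted performance, against the blowfly's:
#' \deqn{p(T_{mean}) = \frac{g\, w_{beetle}}{g\, w_{beetle} + w_{blowfly}}}
#' where the group boost `g >= 1` multiplies the beetle side (1 for solitary
#' pairs, > 1 for cooperative groups). Where both weighted performances are
#' below `eps_den` the contest is out of range: the probability is 0 and a
#' warning is raised.
#'
#' @param t_mean Mean environmental temperature(s), deg C.
#' @param beetle,blowfly [fundamental_tpc()] objects.
#' @param variance_v Environmental temperature variance, deg C^2.
#' @param group_boost Multiplier `g >= 1` on the beetle's side of the contest.
#' @param eps_den Floor below which performances count as zero.
#' @return Success probabilities in \[0, 1\].
#' @export
competition_success_prob <- function(t_mean, beetle, blowfly, variance_v,
                                     group_boost = 1, eps_den = 1e-12) {
  assert_tpc(beetle, "beetle")
  assert_tpc(blowfly, "blowfly")
  if (!(group_boost >= 1)) abort("`group_boost` must be >= 1.")
  w_b <- weighted_performance(t_mean, beetle, variance_v)
  w_f <- weighted_performance(t_mean, blowfly, variance_v)
  out <- numeric(length(w_b))
  dead <- (w_b < eps_den) & (w_f < eps_den)
  if (any(dead)) {
    warn("Both species' weighted performances are ~0 at some temperatures; success probability set to 0 there.")
  }
  live <- !dead
  out[live] <- (group_boost * w_b[live]) /
    (group_boost * w_b[live] + w_f[live])
  out
}

#' @rdname competition_success_prob
#' @param seed Integer seed; draws are deterministic given it.
#' @return `simulate_competition_outcome()` returns Bernoulli outcomes 0/1.
#' @export
simulate_competition_outcome <- function(t_mean, beetle, blowfly, variance_v,
                                         group_boost = 1, seed,
                                         eps_den = 1e-12) {
  if (missing(seed)) abort("`seed` is required: generators are pure functions of (config, seed).")
  p <- competition_success_prob(t_mean, beetle, blowfly, variance_v,
                                group_boost, eps_den)
  withr::with_seed(seed, rbinom(length(p), 1, p))
}
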