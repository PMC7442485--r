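#' Optimal temperature from a fitted quadratic TPC
#'
#' The fitted linear predictor is quadratic in temperature,
#' \eqn{\eta(T) = \beta_0 + \beta_1 T + \beta_2 T^2}; because the logit link
#' is monotone, the fitted success probability peaks at the same vertex,
#' \eqn{T_{optimal} = -\beta_1 / (2\beta_2)}. For models with
#' treatment-by-temperature interactions the arm-specific coefficients are
#' used.
#'
#' @param fit A `tpc_fit` whose spec includes both `T` and `T^2` terms.
#' @param treatment_level Optional treatment level whose arm-specific curve is
#'   summarised (default: reference level).
#' @return The optimal temperature, deg C.
#' @examples
#' # beta1 = 1.2, beta2 = -0.04  =>  T_optimal = 15
#' @export
t_optimal <- function(fit, treatment_level = NULL) {
  stopifnot(inherits(fit, "tpc_fit"))
  ab <- quad_coefs(fit, treatment_level)
  if (!is.finite(ab[["b2"]]) || ab[["b2"]] >= 0) {
    abort("Non-unimodal fit: the quadratic coefficient is not negative, so the curve has no interior maximum.")
  }
  -ab[["b1"]] / (2 * ab[["b2"]])
}

# Arm-specific (b1, b2) on the link scale, folding in interaction terms.
quad_coefs <- function(fit, treatment_level = NULL) {
  beta <- fit$coefficients
  if (!"temperature" %in% names(beta) || !"I(temperature^2)" %in% names(beta)) {
    abort("The fitted model must contain both `T` and `T^2` terms.")
  }
  b1 <- beta[["temperature"]]
  b2 <- beta[["I(temperature^2)"]]
  tr <- fit$spec$treatment
  if (!is.null(tr) && fit$spec$interaction && !is.null(treatment_level)) {
    lev <- fit$xlev[[tr]]
    if (!treatment_level %in% lev) {
      abort(sprintf("Unknown treatment level `%s`.", treatment_level))
    }
    if (treatment_level != lev[1]) {
      # R may order interaction names either way round
      pick <- function(a, b) {
        hit <- intersect(c(paste0(a, ":", b), paste0(b, ":", a)), names(beta))
        if (length(hit)) beta[[hit[1]]] else 0
      }
      b1 <- b1 + pick(paste0(tr, treatment_level), "temperature")
      b2 <- b2 + pick(paste0(tr, treatment_level), "I(temperature^2)")
    }
  }
  c(b1 = b1, b2 = b2)
}

#' TPC breadth from the confidence band of the fitted curve
#'
#' Breadth is the temperature interval over which the fitted curve is
#' statistically distinguishable from zero: the maximal contiguous interval
#' around the fitted optimum where the lower limit of the pointwise
#' (1 - alpha) delta-method band on the probability scale stays above zero.
#' Boundaries are refined by bisection between grid points to 0.01 deg C.
#'
#' @param fit A unimodal `tpc_fit` (quadratic coefficient < 0).
#' @param grid Temperature grid to scan; must cover the fitted optimum.
#'   Defaults to `t_optimal +/- 25` deg C at 0.05 deg C spacing.
#' @param alpha Significance level of the band (default 0.05).
#' @param treatment_level Optional treatment arm.
#' @return One-row tibble: `t_optimal`, `breadth_lo`, `breadth_hi`, `breadth`,
#'   `alpha`. If the band's lower limit never exceeds zero the interval is
#'   empty (`NA` bounds, breadth 0) and a warning is raised.
#' @export
tpc_breadth <- function(fit, grid = NULL, alpha = 0.05, treatment_level = NULL) {
  t_opt <- t_optimal(fit, treatment_level)  # also validates unimodality
  if (is.null(grid)) grid <- seq(t_opt - 25, t_opt + 25, by = 0.05)
  if (t_opt < min(grid) || t_opt > max(grid)) {
    abort("`grid` must cover the fitted optimum.")
  }
  z <- qnorm(1 - alpha / 2)
  lower_fun <- function(t) band_lower(fit, t, treatment_level, z)
  lo_band <- lower_fun(grid)

  positive <- lo_band > 0
  if (!any(positive)) {
    warn("The lower confidence band never exceeds zero; TPC breadth is empty.")
    return(tibble(t_optimal = t_opt, breadth_lo = NA_real_,
                  breadth_hi = NA_real_, breadth = 0, alpha = alpha))
  }

  # contiguous positive run containing (or nearest to) the optimum
  i_opt <- which.min(abs(grid - t_opt))
  runs <- rle(positive)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  containing <- keep[starts[keep] <= i_opt & ends[keep] >= i_opt]
  best <- if (length(containing)) containing[1] else
    keep[which.min(pmin(abs(grid[starts[keep]] - t_opt),
                        abs(grid[ends[keep]] - t_opt)))]
  i0 <- starts[best]; i1 <- ends[best]

  lo <- grid[i0]; hi <- grid[i1]
  if (i0 > 1L) {
    r <- tryCatch(uniroot(lower_fun, c(grid[i0 - 1L], grid[i0]), tol = 0.005),
                  error = function(e) NULL)
    if (!is.null(r)) lo <- r$root
  }
  if (i1 < length(grid)) {
    r <- tryCatch(uniroot(lower_fun, c(grid[i1], grid[i1 + 1L]), tol = 0.005),
                  error = function(e) NULL)
    if (!is.null(r)) hi <- r$root
  }
  tibble(t_optimal = t_opt, breadth_lo = lo, breadth_hi = hi,
         breadth = hi - lo, alpha = alpha)
}

# Lower limit of the pointwise delta-method band, as a bare numeric vector
# (predict_tpc() minus the tibble overhead; called inside root finding).
band_lower <- function(fit, temperature, treatment_level, z) {
  X <- fixed_design_matrix(fit, temperature, treatment_level)
  eta <- drop(X %*% fit$coefficients)
  se_eta <- sqrt(pmax(rowSums((X %*% fit$vcov) * X), 0))
  if (fit$spec$family == "binomial") {
    p <- plogis(eta)
    p - z * p * (1 - p) * se_eta
  } else {
    eta - z * se_eta
  }
}

#' Likelihood-ratio test of nested TPC models
#'
#' Twice the log-likelihood difference between a full and a nested reduced
#' model, referred to a chi-squared distribution with degrees of freedom equal
#' to the difference in fixed-effect count. This is the 2-df "temperature
#' effect" test when the full model adds `T` and `T^2` to an intercept-only
#' model. The statistic is clamped at zero for boundary cases.
#'
#' @param full,reduced `tpc_fit` objects on the same records, same family and
#'   random structure, with `reduced` nested in `full`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `test_type`.
#' @examples
#' # pchisq(26.29, df = 2, lower.tail = FALSE) < 0.001
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "tpc_fit"), inherits(reduced, "tpc_fit"))
  if (!spec_nested(full$spec, reduced$spec)) {
    abort("`reduced` is not nested in `full` (same family, random structure, and a subset of fixed terms are required).")
  }
  if (full$n != reduced$n) {
    abort("`full` and `reduced` must be fitted to the same records.")
  }
  df <- length(full$coefficients) - length(reduced$coefficients)
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  tibble(statistic = stat, df = df, p_value = p, test_type = "LRT")
}

#' Two-df temperature-effect test
#'
#' Convenience wrapper reproducing the field's standard unimodality test:
#' fits the quadratic model and the model with temperature terms removed, and
#' runs the 2-df likelihood-ratio test of {T, T^2}.
#'
#' @param data Trial records.
#' @param spec A quadratic [tpc_model_spec()] (`degree = 2`).
#' @return One-row tibble as from [lr_test()].
#' @export
temperature_lrt <- function(data, spec = tpc_model_spec()) {
  if (spec$degree != 2) abort("`spec` must be quadratic (`degree = 2`).")
  if (spec$interaction) abort("Use `compare_tpcs()` for interaction tests.")
  reduced_spec <- tpc_model_spec(response = spec$response, degree = 0,
                                 treatment = spec$treatment,
                                 random = spec$random, family = spec$family)
  full <- fit_tpc(data, spec, quiet = TRUE)
  reduced <- fit_tpc(data, reduced_spec, quiet = TRUE)
  lr_test(full, reduced)
}

#' Test whether TPCs differ between treatment arms
#'
#' Likelihood-ratio test of the treatment-by-temperature interaction: the
#' model with `treatment x {T, T^2}` interactions against the model with the
#' treatment main effect only. With L treatment levels the test has
#' `2 * (L - 1)` degrees of freedom. A significant result means the arms'
#' thermal performance curves differ in shape or optimum, not merely in
#' height.
#'
#' @param data Trial records containing the treatment column.
#' @param spec A [tpc_model_spec()] with `treatment` set and
#'   `interaction = TRUE`.
#' @return One-row tibble as from [lr_test()], plus the two fits as
#'   attributes `full` and `reduced`.
#' @export
compare_tpcs <- function(data, spec) {
  if (is.null(spec$treatment) || !spec$interaction) {
    abort("`spec` must set `treatment` and `interaction = TRUE`.")
  }
  if (spec$degree != 2) abort("`spec` must be quadratic (`degree = 2`).")
  reduced_spec <- tpc_model_spec(response = spec$response, degree = 2,
                                 treatment = spec$treatment,
                                 interaction = FALSE,
                                 random = spec$random, family = spec$family)
  full <- fit_tpc(data, spec, quiet = TRUE)
  reduced <- fit_tpc(data, reduced_spec, quiet = TRUE)
  out <- lr_test(full, reduced)
  attr(out, "full") <- full
  attr(out, "reduced") <- reduced
  out
}
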