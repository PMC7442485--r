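#' Fit a thermal-performance regression model
#'
#' Fits the model described by a [tpc_model_spec()] to trial records:
#' a logistic GLM ([stats::glm()]) when no random intercepts are requested, a
#' logistic GLMM with Laplace-approximated marginal likelihood
#' ([lme4::glmer()]) when they are, or an ordinary least-squares fit
#' ([stats::lm()]) for Gaussian responses. Records with a missing response are
#' dropped (with a reported count) before fitting, matching the treatment of
#' trials excluded in the field (e.g. deaths during an experiment).
#'
#' Binomial fits require both successes and failures to be present; complete
#' or quasi-complete separation (any coefficient beyond 25 on the logit scale)
#' is reported as an error rather than returned as a silently diverged fit.
#'
#' @param data A data frame of trial records with (at least) the columns named
#'   by the spec: the response, `temperature`, and any treatment / grouping
#'   columns.
#' @param spec A [tpc_model_spec()].
#' @param quiet If `TRUE`, suppress the dropped-row message.
#' @return An object of class `tpc_fit`: a list with elements `coefficients`
#'   (fixed effects, link scale), `vcov` (their covariance), `re_variances`
#'   (named random-intercept variances, possibly empty), `loglik`, `n`,
#'   `n_dropped`, `converged`, `spec`, `model` (the underlying fit) and
#'   `xlev` (treatment factor levels).
#' @examples
#' truth <- coeffs_from_shape(t_opt = 15.6, p_max = 0.7, h = 4.7)
#' lab <- simulate_lab(truth, n_per_temp = 30, seed = 42)
#' fit <- fit_tpc(lab, tpc_model_spec())
#' t_optimal(fit)
#' @export
fit_tpc <- function(data, spec, quiet = FALSE) {
  if (!inherits(spec, "tpc_model_spec")) {
    abort("`spec` must be a `tpc_model_spec` object.")
  }
  data <- as_tibble(data)
  required <- c(spec$response, if (spec$degree >= 1) "temperature",
                spec$treatment, spec$random)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns in `data`: ",
                 paste(missing_cols, collapse = ", "), "."))
  }

  n_in <- nrow(data)
  data <- data[!is.na(data[[spec$response]]), , drop = FALSE]
  n_dropped <- n_in - nrow(data)
  if (n_dropped > 0 && !quiet) {
    inform(sprintf("Dropped %d record(s) with missing `%s`.",
                   n_dropped, spec$response))
  }
  if (nrow(data) == 0) abort("No usable records after dropping missing responses.")

  if (spec$degree >= 1 && any(!is.finite(data$temperature))) {
    abort("`temperature` must be finite for all fitted records.")
  }
  xlev <- NULL
  if (!is.null(spec$treatment)) {
    data[[spec$treatment]] <- factor(data[[spec$treatment]])
    xlev <- setNames(list(levels(data[[spec$treatment]])), spec$treatment)
    if (nlevels(data[[spec$treatment]]) < 2) {
      abort(sprintf("Treatment `%s` must have at least 2 levels.", spec$treatment))
    }
  }
  for (g in spec$random) {
    data[[g]] <- factor(data[[g]])
    if (any(is.na(data[[g]])) || any(data[[g]] == "")) {
      abort(sprintf("Random factor `%s` has missing levels.", g))
    }
    if (nlevels(data[[g]]) < 2) {
      abort(sprintf("Random factor `%s` is singular: it needs >= 2 levels.", g))
    }
  }

  if (spec$family == "binomial") {
    y <- data[[spec$response]]
    if (!all(y %in% c(0, 1))) {
      abort(sprintf("`%s` must be binary 0/1 for binomial fits.", spec$response))
    }
    if (length(unique(y)) < 2) {
      abort("Degenerate data: all outcomes identical; a binomial TPC cannot be fitted.")
    }
  }

  f <- spec_formula(spec)
  if (spec$family == "gaussian") {
    if (length(spec$random) > 0) {
      abort("Gaussian mixed models are not supported; use an empty `random`.")
    }
    m <- lm(f, data = data)
    if (any(is.na(coef(m)))) {
      abort("Collinearity: the design matrix is rank deficient.")
    }
    beta <- coef(m)
    V <- vcov(m)
    re <- numeric(0)
    ll <- as.numeric(logLik(m))
    converged <- TRUE
  } else if (length(spec$random) == 0) {
    m <- suppressWarnings(glm(f, family = binomial(), data = data))
    beta <- coef(m)
    if (any(is.na(beta))) abort("Collinearity: the design matrix is rank deficient.")
    # separation: the linear predictor runs away (> 25 logits pins fitted
    # probabilities at 0/1 far beyond anything the data can support)
    if (max(abs(predict(m, type = "link"))) > 25) {
      abort("Separation: the fitted linear predictor exceeds 25 logits; the MLE does not exist (complete or quasi-complete separation).")
    }
    V <- vcov(m)
    re <- numeric(0)
    ll <- as.numeric(logLik(m))
    converged <- m$converged
  } else {
    m <- suppressMessages(suppressWarnings(
      lme4::glmer(f, family = binomial(), data = data,
                  control = lme4::glmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
    ))
    beta <- lme4::fixef(m)
    V <- as.matrix(vcov(m))
    vc <- lme4::VarCorr(m)
    re <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
    ll <- as.numeric(logLik(m))
    converged <- length(m@optinfo$conv$lme4) == 0 ||
      is.null(m@optinfo$conv$lme4$code)
    if (!converged) {
      warn("GLMM fit did not converge cleanly; inspect `$model` diagnostics.")
    }
  }

  structure(
    list(coefficients = beta, vcov = V, re_variances = re, loglik = ll,
         n = nrow(data), n_dropped = n_dropped, converged = converged,
         spec = spec, model = m, xlev = xlev, data = data),
    class = "tpc_fit"
  )
}

#' Fit wrappers for the three model families
#'
#' Thin, intention-revealing wrappers around [fit_tpc()]: `fit_binomial_glm()`
#' refuses random intercepts, `fit_binomial_glmm()` requires at least one, and
#' `fit_gaussian_lm()` requires a Gaussian spec.
#'
#' @inheritParams fit_tpc
#' @return A `tpc_fit` (see [fit_tpc()]).
#' @export
fit_binomial_glm <- function(data, spec = tpc_model_spec(), quiet = FALSE) {
  if (spec$family != "binomial" || length(spec$random) > 0) {
    abort("`fit_binomial_glm()` needs a binomial spec with no random intercepts.")
  }
  fit_tpc(data, spec, quiet = quiet)
}

#' @rdname fit_binomial_glm
#' @export
fit_binomial_glmm <- function(data,
                              spec = tpc_model_spec(random = c("plot_id", "year")),
                              quiet = FALSE) {
  if (spec$family != "binomial" || length(spec$random) == 0) {
    abort("`fit_binomial_glmm()` needs a binomial spec with >= 1 random intercept.")
  }
  fit_tpc(data, spec, quiet = quiet)
}

#' @rdname fit_binomial_glm
#' @export
fit_gaussian_lm <- function(data,
                            spec = tpc_model_spec(response = "response_value",
                                                  family = "gaussian"),
                            quiet = FALSE) {
  if (spec$family != "gaussian") {
    abort("`fit_gaussian_lm()` needs a Gaussian spec.")
  }
  fit_tpc(data, spec, quiet = quiet)
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("<tpc_fit> %s, n = %d%s\n", x$spec$family, x$n,
              if (x$n_dropped > 0) sprintf(" (%d dropped)", x$n_dropped) else ""))
  print(round(x$coefficients, 5))
  if (length(x$re_variances) > 0) {
    cat("Random-intercept variances:\n")
    print(round(x$re_variances, 5))
  }
  cat(sprintf("logLik = %.4f, converged = %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @method tidy tpc_fit
#' @export
tidy.tpc_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' @method glance tpc_fit
#' @export
glance.tpc_fit <- function(x, ...) {
  out <- tibble(
    n = x$n, n_dropped = x$n_dropped, logLik = x$loglik,
    df = length(x$coefficients) + length(x$re_variances) +
      (x$spec$family == "gaussian"),
    converged = x$converged, family = x$spec$family
  )
  if (length(x$re_variances) > 0) {
    re <- as.list(setNames(sqrt(x$re_variances),
                           paste0("sigma_", names(x$re_variances))))
    out <- dplyr::bind_cols(out, as_tibble(re))
  }
  out
}

# Fixed-effects design matrix for new temperatures (population-level
# prediction for GLMMs), with columns aligned to the fitted coefficients.
# Built directly from the coefficient names rather than via model.matrix():
# prediction is called inside root-finding loops, where formula parsing
# would dominate the cost.
fixed_design_matrix <- function(fit, temperature, treatment_level = NULL) {
  spec <- fit$spec
  n <- length(temperature)
  if (!is.null(spec$treatment)) {
    lev <- fit$xlev[[spec$treatment]]
    treatment_level <- treatment_level %||% lev[1]
    if (!treatment_level %in% lev) {
      abort(sprintf("Unknown treatment level `%s` (have: %s).",
                    treatment_level, paste(lev, collapse = ", ")))
    }
  }
  base_col <- function(nm) {
    if (nm == "(Intercept)") return(rep(1, n))
    if (nm == "temperature") return(temperature)
    if (nm == "I(temperature^2)") return(temperature^2)
    if (!is.null(spec$treatment) &&
        startsWith(nm, spec$treatment) &&
        substring(nm, nchar(spec$treatment) + 1) %in% fit$xlev[[spec$treatment]]) {
      return(rep(as.numeric(substring(nm, nchar(spec$treatment) + 1) ==
                              treatment_level), n))
    }
    abort(sprintf("Internal error: unrecognised design term `%s`.", nm))
  }
  col_for <- function(nm) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, lapply(parts, base_col))
  }
  X <- vapply(names(fit$coefficients), col_for, numeric(n))
  if (n == 1) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(fit$coefficients)))
  X
}

#' Predicted performance curve with a pointwise confidence band
#'
#' Predicts the fitted response curve over a temperature grid, with a
#' pointwise Wald (1 - alpha) confidence band. For binomial fits the band is
#' computed on the response (probability) scale by the delta method:
#' \eqn{\hat p \pm z_{1-\alpha/2}\, \hat p (1 - \hat p)\, se(\hat\eta)}. The
#' band is symmetric around the fitted curve and its lower limit may cross
#' zero — which is exactly what the TPC-breadth rule exploits. For GLMMs the
#' prediction is at the population level (random effects at zero), using the
#' fixed-effect covariance.
#'
#' @param fit A `tpc_fit`.
#' @param temperature Temperature grid, deg C.
#' @param treatment_level Treatment level to predict for (default: reference
#'   level).
#' @param alpha Significance level for the band (default 0.05).
#' @return A tibble with columns `temperature`, `eta`, `se_eta`, `p_hat`,
#'   `lo`, `hi`.
#' @export
predict_tpc <- function(fit, temperature, treatment_level = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "tpc_fit"))
  X <- fixed_design_matrix(fit, temperature, treatment_level)
  eta <- drop(X %*% fit$coefficients)
  se_eta <- sqrt(pmax(rowSums((X %*% fit$vcov) * X), 0))
  z <- qnorm(1 - alpha / 2)
  if (fit$spec$family == "binomial") {
    p <- plogis(eta)
    se_p <- p * (1 - p) * se_eta
    tibble(temperature = temperature, eta = eta, se_eta = se_eta,
           p_hat = p, lo = p - z * se_p, hi = p + z * se_p)
  } else {
    tibble(temperature = temperature, eta = eta, se_eta = se_eta,
           p_hat = eta, lo = eta - z * se_eta, hi = eta + z * se_eta)
  }
}
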