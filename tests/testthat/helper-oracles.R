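# Independent oracles used across the suite. These deliberately avoid the
# package's own quadrature / optimizer code paths.

# Midpoint-Riemann brute-force integral of performance x Gaussian density
# over [t_mean - 10 sqrt(V), t_mean + 10 sqrt(V)].
riemann_weighted_performance <- function(t_mean, tpc, variance_v,
                                         n_slices = 1e6) {
  s <- sqrt(variance_v)
  lo <- t_mean - 10 * s
  hi <- t_mean + 10 * s
  dt <- (hi - lo) / n_slices
  mid <- lo + (seq_len(n_slices) - 0.5) * dt
  sum(tpc_performance(mid, tpc) * dnorm(mid, t_mean, s)) * dt
}

# Bernoulli log-likelihood of a quadratic-logit model.
bernoulli_loglik <- function(beta, temperature, y) {
  eta <- beta[1] + beta[2] * temperature + beta[3] * temperature^2
  sum(y * eta - log1p(exp(eta)))
}

# Exact marginal log-likelihood of a one-factor random-intercept logistic
# model, integrating each group's likelihood over its intercept numerically.
exact_glmm_loglik <- function(beta, sigma, data, group = "plot_id") {
  eta0 <- beta[1] + beta[2] * data$temperature + beta[3] * data$temperature^2
  total <- 0
  for (g in unique(data[[group]])) {
    idx <- data[[group]] == g
    f <- function(u) {
      vapply(u, function(ui) {
        p <- plogis(eta0[idx] + ui)
        prod(ifelse(data$outcome[idx] == 1, p, 1 - p)) * dnorm(ui, 0, sigma)
      }, numeric(1))
    }
    total <- total + log(integrate(f, -8 * sigma - 1, 8 * sigma + 1,
                                   abs.tol = 1e-12)$value)
  }
  total
}

# Random valid fundamental TPCs for property tests.
random_tpc <- function() {
  t_opt <- runif(1, 5, 25)
  fundamental_tpc(
    t_opt = t_opt,
    t_max = t_opt + runif(1, 4, 15),
    sigma_p = runif(1, 1, 8)
  )
}

# A fabricated tpc_fit with known coefficients/covariance, for closed-form
# checks of t_optimal / tpc_breadth that do not depend on a fitting step.
fake_quadratic_fit <- function(beta, vcov = diag(1e-12, 3)) {
  beta <- setNames(beta, c("(Intercept)", "temperature", "I(temperature^2)"))
  dimnames(vcov) <- list(names(beta), names(beta))
  structure(
    list(coefficients = beta, vcov = vcov, re_variances = numeric(0),
         loglik = NA_real_, n = NA_integer_, n_dropped = 0L, converged = TRUE,
         spec = tpc_model_spec(), model = NULL, xlev = NULL, data = NULL),
    class = "tpc_fit"
  )
}
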