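#' Define a fundamental thermal performance curve
#'
#' A fundamental TPC describes performance as a function of temperature in the
#' absence of biotic interactions. The curve has a Gaussian cold limb below the
#' optimum, a quadratic warm limb between the optimum and the upper critical
#' temperature, and is exactly zero above it:
#' \deqn{P(T) = \exp\{-((T - T_{opt})/(2\sigma_p))^2\}, \quad T \le T_{opt}}
#' \deqn{P(T) = 1 - ((T - T_{opt})/(T_{opt} - T_{max}))^2, \quad T_{opt} < T \le T_{max}}
#' \deqn{P(T) = 0, \quad T > T_{max}}
#'
#' @param t_opt Optimal temperature (deg C), where performance peaks at 1.
#' @param t_max Upper critical temperature (deg C); performance is zero above
#'   it. Must exceed `t_opt`.
#' @param sigma_p Shape parameter (deg C) controlling the steepness of the
#'   cold limb; must be positive.
#' @param label Free-text label, e.g. `"specialist"` or `"generalist"`.
#'
#' @return An object of class `fundamental_tpc`.
#' @examples
#' beetle <- fundamental_tpc(t_opt = 16, t_max = 26, sigma_p = 4, label = "specialist")
#' tpc_performance(c(12, 16, 21, 26, 31), beetle)
#' @export
fundamental_tpc <- function(t_opt, t_max, sigma_p, label = "species") {
  stopifnot(is.numeric(t_opt), is.numeric(t_max), is.numeric(sigma_p),
            length(t_opt) == 1, length(t_max) == 1, length(sigma_p) == 1)
  if (!is.finite(sigma_p) || sigma_p <= 0) {
    abort("`sigma_p` must be a positive, finite temperature (deg C).")
  }
  if (!is.finite(t_opt) || !is.finite(t_max) || t_opt >= t_max) {
    abort("`t_opt` must be finite and strictly below `t_max`.")
  }
  structure(
    list(t_opt = t_opt, t_max = t_max, sigma_p = sigma_p,
         label = as.character(label)),
    class = "fundamental_tpc"
  )
}

#' @export
print.fundamental_tpc <- function(x, ...) {
  cat(sprintf("<fundamental_tpc> %s: t_opt = %g, t_max = %g, sigma_p = %g\n",
              x$label, x$t_opt, x$t_max, x$sigma_p))
  invisible(x)
}

is_fundamental_tpc <- function(x) inherits(x, "fundamental_tpc")

assert_tpc <- function(x, arg = "tpc") {
  if (!is_fundamental_tpc(x)) {
    abort(sprintf("`%s` must be a `fundamental_tpc` object.", arg))
  }
  invisible(x)
}

#' Evaluate a fundamental TPC
#'
#' Vectorised over `t`. Performance lies in \[0, 1\], peaks at 1 when
#' `t == t_opt`, and is exactly 0 for `t > t_max`. The curve is continuous at
#' both the optimum and the upper critical temperature.
#'
#' @param t Temperature(s), deg C.
#' @param tpc A [fundamental_tpc()].
#' @return Numeric vector of performances in \[0, 1\].
#' @export
tpc_performance <- function(t, tpc) {
  assert_tpc(tpc)
  cold <- exp(-((t - tpc$t_opt) / (2 * tpc$sigma_p))^2)
  warm <- 1 - ((t - tpc$t_opt) / (tpc$t_opt - tpc$t_max))^2
  out <- ifelse(t <= tpc$t_opt, cold, warm)
  out[t > tpc$t_max] <- 0
  out
}

#' Gaussian environmental temperature density
#'
#' The chance of encountering temperature `t` in an environment with mean
#' temperature `t_mean` and temperature variance `variance_v` (deg C squared):
#' a Gaussian density \eqn{(2\pi V)^{-1/2} \exp\{-(t - T_{mean})^2 / (2V)\}}.
#'
#' @param t Temperature(s), deg C.
#' @param t_mean Mean environmental temperature, deg C.
#' @param variance_v Environmental temperature variability V, deg C^2 (> 0).
#' @return Density values (1/deg C).
#' @export
env_density <- function(t, t_mean, variance_v) {
  if (!is.numeric(variance_v) || variance_v <= 0) {
    abort("`variance_v` must be a positive temperature variance (deg C^2).")
  }
  dnorm(t, mean = t_mean, sd = sqrt(variance_v))
}

#' Temperature-weighted performance
#'
#' Integrates performance against the Gaussian distribution of temperatures an
#' organism experiences at a given mean temperature:
#' \deqn{w(T_{mean}) = \int P(t)\, f(t \mid T_{mean})\, dt.}
#'
#' The integral is computed by adaptive quadrature on the standardised scale
#' \eqn{z = (t - T_{mean})/\sqrt{V}} over \eqn{z \in [-10, 10]}, split at the
#' curve's kink (`t_opt`) and cutoff (`t_max`) so the integrand is smooth on
#' each piece; performance is exactly zero above `t_max`, so the truncation is
#' lossless. Standardising keeps the quadrature stable down to vanishing
#' variance, where \eqn{w \to P(T_{mean})}.
#'
#' @param t_mean Mean environmental temperature(s), deg C; vectorised.
#' @param tpc A [fundamental_tpc()].
#' @param variance_v Environmental temperature variance V, deg C^2 (> 0).
#' @param abs_tol Absolute tolerance for the quadrature.
#' @return Weighted performance value(s) in \[0, 1\].
#' @examples
#' w <- weighted_performance(15, fundamental_tpc(16, 26, 4), variance_v = 9)
#' @export
weighted_performance <- function(t_mean, tpc, variance_v, abs_tol = 1e-8) {
  assert_tpc(tpc)
  if (!is.numeric(variance_v) || length(variance_v) != 1 || variance_v <= 0) {
    abort("`variance_v` must be a single positive variance (deg C^2).")
  }
  vapply(t_mean, weighted_performance_one, numeric(1),
         tpc = tpc, variance_v = variance_v, abs_tol = abs_tol)
}

weighted_performance_one <- function(t_mean, tpc, variance_v, abs_tol) {
  s <- sqrt(variance_v)
  # z-locations of the kink and the hard cutoff
  z_breaks <- sort(unique(pmin(pmax(
    c((tpc$t_opt - t_mean) / s, (tpc$t_max - t_mean) / s), -10), 10)))
  hi <- min(10, (tpc$t_max - t_mean) / s)
  if (hi <= -10) return(0)  # environment lies entirely above t_max
  pts <- sort(unique(c(-10, z_breaks[z_breaks > -10 & z_breaks < hi], hi)))
  f <- function(z) tpc_performance(t_mean + z * s, tpc) * dnorm(z)
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    piece <- tryCatch(
      integrate(f, pts[i], pts[i + 1], abs.tol = abs_tol / (length(pts) - 1),
                rel.tol = 1e-10, subdivisions = 400L),
      error = function(e) NULL
    )
    if (is.null(piece) || piece$message != "OK") {
      abort(sprintf(
        "Quadrature failed for weighted performance at t_mean = %g (t_opt = %g, t_max = %g, sigma_p = %g, V = %g).",
        t_mean, tpc$t_opt, tpc$t_max, tpc$sigma_p, variance_v))
    }
    total <- total + piece$value
  }
  min(max(total, 0), 1)
}

#' Relative performance of two competing species
#'
#' The ratio of the focal species' temperature-weighted performance to its
#' competitor's, \eqn{w_{focal}(T_{mean}) / w_{comp}(T_{mean})}. Where the
#' competitor's weighted performance falls below a floor (`eps_den`,
#' default 1e-12) — i.e. beyond both species' viable range — the ratio is
#' undefined and `NA` is returned rather than an arbitrarily large number.
#'
#' @param t_mean Mean environmental temperature(s), deg C; vectorised.
#' @param focal,competitor [fundamental_tpc()] objects.
#' @param variance_v Environmental temperature variance, deg C^2.
#' @param eps_den Denominator floor below which the ratio is undefined.
#' @return Numeric vector of ratios (>= 0), `NA` where undefined.
#' @export
relative_performance <- function(t_mean, focal, competitor, variance_v,
                                 eps_den = 1e-12) {
  assert_tpc(focal, "focal")
  assert_tpc(competitor, "competitor")
  w_f <- weighted_performance(t_mean, focal, variance_v)
  w_c <- weighted_performance(t_mean, competitor, variance_v)
  ifelse(w_c < eps_den, NA_real_, w_f / w_c)
}
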