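#' Construct a realized TPC from two competing fundamental TPCs
#'
#' The realized TPC of a focal species facing a competitor is its relative
#' temperature-weighted performance \eqn{w_{focal}/w_{comp}} across mean
#' environmental temperatures. The curve is tabulated on a temperature grid;
#' its optimum is the refined argmax of the ratio and its width is the maximal
#' contiguous interval over which the focal species outperforms its competitor
#' (ratio >= 1, the equal-performance line).
#'
#' The optimum is refined between the bracketing grid neighbours with
#' [stats::optimize()] (golden-section/parabolic search, tolerance 1e-4 deg C);
#' interval boundaries are located between grid points with [stats::uniroot()]
#' to the same tolerance. A flat ratio curve (max - min < 1e-9) has no defined
#' optimum and `t_optimal` is `NA`.
#'
#' @param focal,competitor [fundamental_tpc()] objects.
#' @param variance_v Environmental temperature variance, deg C^2.
#' @param grid Strictly increasing temperature grid (>= 3 points). Defaults to
#'   0.05 deg C spacing spanning
#'   `min(t_opt) - 4 * max(sigma_p)` to `max(t_max)`.
#' @param eps_den Denominator floor passed to [relative_performance()].
#' @return An object of class `realized_tpc`: a list with `curve` (a tibble
#'   with columns `t_mean`, `w_focal`, `w_competitor`, `ratio`), `t_optimal`,
#'   `width_interval`, `width`, and the inputs.
#' @examples
#' sp <- fundamental_tpc(16, 26, 4, "specialist")
#' ge <- fundamental_tpc(23, 35, 9, "generalist")
#' rt <- realized_tpc(sp, ge, variance_v = 4)
#' rt$t_optimal  # below the specialist's fundamental optimum of 16
#' @export
realized_tpc <- function(focal, competitor, variance_v, grid = NULL,
                         eps_den = 1e-12) {
  assert_tpc(focal, "focal")
  assert_tpc(competitor, "competitor")
  if (is.null(grid)) {
    lo <- min(focal$t_opt, competitor$t_opt) -
      4 * max(focal$sigma_p, competitor$sigma_p)
    hi <- max(focal$t_max, competitor$t_max)
    grid <- seq(lo, hi, by = 0.05)
  }
  if (length(grid) < 3 || any(diff(grid) <= 0)) {
    abort("`grid` must be strictly increasing with at least 3 points.")
  }
  w_f <- weighted_performance(grid, focal, variance_v)
  w_c <- weighted_performance(grid, competitor, variance_v)
  ratio <- ifelse(w_c < eps_den, NA_real_, w_f / w_c)
  if (all(is.na(ratio))) {
    abort("Empty domain: the relative performance is undefined over the whole grid.")
  }
  ratio_fun <- function(t) {
    wc <- weighted_performance(t, competitor, variance_v)
    if (wc < eps_den) return(NA_real_)
    weighted_performance(t, focal, variance_v) / wc
  }

  ok <- which(!is.na(ratio))
  flat <- (max(ratio[ok]) - min(ratio[ok])) < 1e-9
  if (flat) {
    t_optimal <- NA_real_
  } else {
    i <- ok[which.max(ratio[ok])]
    lo_i <- grid[max(i - 1L, 1L)]
    hi_i <- grid[min(i + 1L, length(grid))]
    opt <- optimize(function(t) {
      r <- ratio_fun(t)
      if (is.na(r)) -1e300 else r  # undefined ratio never wins the search
    }, lower = lo_i, upper = hi_i, maximum = TRUE, tol = 1e-4)
    t_optimal <- opt$maximum
  }

  width_interval <- locate_level_interval(grid, ratio, level = 1,
                                          fun = function(t) ratio_fun(t) - 1)
  width <- if (is.null(width_interval)) 0 else diff(width_interval)

  structure(
    list(
      curve = tibble(t_mean = grid, w_focal = w_f, w_competitor = w_c,
                     ratio = ratio),
      t_optimal = t_optimal,
      width_interval = width_interval %||% c(NA_real_, NA_real_),
      width = width,
      focal = focal, competitor = competitor, variance_v = variance_v
    ),
    class = "realized_tpc"
  )
}

# Maximal contiguous run of grid points with values >= level, boundaries
# refined by root finding (fun = values - level as a continuous function)
# between the bracketing grid points. Returns c(lo, hi) or NULL.
locate_level_interval <- function(grid, values, level, fun = NULL,
                                  tol = 1e-4) {
  above <- !is.na(values) & values >= level
  if (!any(above)) return(NULL)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  best <- keep[which.max(grid[ends[keep]] - grid[starts[keep]])]
  i0 <- starts[best]; i1 <- ends[best]

  lo <- grid[i0]; hi <- grid[i1]
  if (!is.null(fun)) {
    if (i0 > 1L && !is.na(values[i0 - 1L]) && values[i0 - 1L] < level) {
      r <- tryCatch(uniroot(fun, c(grid[i0 - 1L], grid[i0]), tol = tol),
                    error = function(e) NULL)
      if (!is.null(r)) lo <- r$root
    }
    if (i1 < length(grid) && !is.na(values[i1 + 1L]) && values[i1 + 1L] < level) {
      r <- tryCatch(uniroot(fun, c(grid[i1], grid[i1 + 1L]), tol = tol),
                    error = function(e) NULL)
      if (!is.null(r)) hi <- r$root
    }
  }
  c(lo, hi)
}

#' @export
print.realized_tpc <- function(x, ...) {
  cat(sprintf("<realized_tpc> %s vs %s (V = %g)\n",
              x$focal$label, x$competitor$label, x$variance_v))
  cat(sprintf("  t_optimal: %s deg C\n",
              if (is.na(x$t_optimal)) "undefined (flat)" else
                format(x$t_optimal, digits = 5)))
  if (!any(is.na(x$width_interval))) {
    cat(sprintf("  outperformance interval (ratio >= 1): [%.3f, %.3f], width %.3f deg C\n",
                x$width_interval[1], x$width_interval[2], x$width))
  } else {
    cat("  outperformance interval: empty\n")
  }
  invisible(x)
}

#' Tabulate a fundamental TPC on a grid
#'
#' @param tpc A [fundamental_tpc()].
#' @param grid Temperature grid; defaults to 0.05 deg C spacing over
#'   `t_opt - 4 sigma_p` to `t_max`.
#' @return A tibble with columns `temperature` and `performance`.
#' @export
fundamental_curve <- function(tpc, grid = NULL) {
  assert_tpc(tpc)
  if (is.null(grid)) grid <- seq(tpc$t_opt - 4 * tpc$sigma_p, tpc$t_max, by = 0.05)
  tibble(temperature = grid, performance = tpc_performance(grid, tpc))
}

#' Summarise a tabulated performance curve
#'
#' Generic optimum/width extractor for tabulated curves (fundamental or
#' realized). The optimum is the argmax refined by quadratic interpolation
#' through the three points bracketing the grid maximum; the width is the
#' maximal contiguous interval where the curve stays at or above
#' `level * max(values)`, with boundaries linearly interpolated between grid
#' points. All-equal values yield an undefined (`NA`) optimum and a
#' full-grid interval.
#'
#' @param grid Strictly increasing temperature vector (length >= 3).
#' @param values Curve values, same length as `grid`.
#' @param level Width level as a fraction of the curve maximum (default
#'   half-max).
#' @return One-row tibble: `t_optimal`, `width_lo`, `width_hi`, `width`.
#' @examples
#' g <- seq(0, 26, by = 0.01)
#' curve_summary(g, tpc_performance(g, fundamental_tpc(16, 26, 4)))
#' @export
curve_summary <- function(grid, values, level = 0.5) {
  if (length(grid) != length(values) || length(grid) < 3) {
    abort("`grid` and `values` must have equal length >= 3.")
  }
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing.")
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort("`level` must lie in (0, 1).")
  }
  ok <- !is.na(values)
  if (!any(ok)) abort("All curve values are missing.")
  vmax <- max(values[ok]); vmin <- min(values[ok])

  if (vmax - vmin < 1e-9) {
    return(tibble(t_optimal = NA_real_, width_lo = grid[1],
                  width_hi = grid[length(grid)],
                  width = grid[length(grid)] - grid[1]))
  }

  i <- which.max(ifelse(ok, values, -Inf))
  t_optimal <- refine_argmax(grid, values, i)

  thr <- level * vmax
  iv <- interp_level_interval(grid, values, thr)
  tibble(t_optimal = t_optimal, width_lo = iv[1], width_hi = iv[2],
         width = iv[2] - iv[1])
}

# Parabolic refinement of a tabulated argmax; falls back to the grid point at
# the edges or when the local quadratic degenerates.
refine_argmax <- function(grid, values, i) {
  n <- length(grid)
  if (i == 1L || i == n) return(grid[i])
  x <- grid[(i - 1L):(i + 1L)]; y <- values[(i - 1L):(i + 1L)]
  if (any(is.na(y))) return(grid[i])
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
  if (a >= 0) return(grid[i])
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
  vertex <- -b / (2 * a)
  if (vertex < x[1] || vertex > x[3]) grid[i] else vertex
}

interp_level_interval <- function(grid, values, thr) {
  above <- !is.na(values) & values >= thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  best <- keep[which.max(grid[ends[keep]] - grid[starts[keep]])]
  i0 <- starts[best]; i1 <- ends[best]
  lo <- grid[i0]; hi <- grid[i1]
  if (i0 > 1L && !is.na(values[i0 - 1L])) {
    lo <- grid[i0 - 1L] + (thr - values[i0 - 1L]) /
      (values[i0] - values[i0 - 1L]) * (grid[i0] - grid[i0 - 1L])
  }
  if (i1 < length(grid) && !is.na(values[i1 + 1L])) {
    hi <- grid[i1] + (thr - values[i1]) /
      (values[i1 + 1L] - values[i1]) * (grid[i1 + 1L] - grid[i1])
  }
  c(lo, hi)
}

#' Theory curves for a pair of competitors
#'
#' Convenience tabulation used by the reporting pipeline: fundamental and
#' weighted performance of both species plus the two reciprocal relative
#' performance ratios on a shared grid.
#'
#' @inheritParams realized_tpc
#' @return A tibble with columns `t_mean`, `w_focal`, `w_competitor`, `ratio`
#'   (focal/competitor) and `ratio_competitor` (competitor/focal).
#' @export
theory_curves <- function(focal, competitor, variance_v, grid = NULL) {
  rt <- realized_tpc(focal, competitor, variance_v, grid)
  dplyr::mutate(
    rt$curve,
    ratio_competitor = ifelse(.data$w_focal < 1e-12, NA_real_,
                              .data$w_competitor / .data$w_focal)
  )
}
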