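#' Plot a fundamental TPC
#'
#' @param object A [fundamental_tpc()].
#' @param grid Optional temperature grid.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fundamental_tpc
#' @export
autoplot.fundamental_tpc <- function(object, grid = NULL, ...) {
  fc <- fundamental_curve(object, grid)
  ggplot2::ggplot(fc, ggplot2::aes(x = .data$temperature, y = .data$performance)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$t_opt, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Temperature (°C)", y = "Performance",
                  title = object$label) +
    ggplot2::theme_minimal()
}

#' Plot a realized TPC (relative performance curve)
#'
#' Shows the focal-to-competitor performance ratio against mean temperature,
#' the equal-performance line (ratio = 1), and the realized optimum.
#'
#' @param object A [realized_tpc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot realized_tpc
#' @export
autoplot.realized_tpc <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$t_mean, y = .data$ratio)) +
    ggplot2::geom_line(linewidth = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "Mean temperature (°C)",
      y = sprintf("Relative performance  w(%s) / w(%s)",
                  object$focal$label, object$competitor$label)
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$t_optimal)) {
    p <- p + ggplot2::geom_vline(xintercept = object$t_optimal,
                                 linetype = "dotted", colour = "grey40")
  }
  p
}

#' Plot a fitted TPC with its confidence band and binned data
#'
#' Overlays the fitted success-probability curve and its pointwise confidence
#' band on empirical success rates in temperature bins. For models with
#' treatment interactions, one curve per arm is drawn.
#'
#' @param object A `tpc_fit` (binomial).
#' @param bin_width Width of temperature bins for the empirical points, deg C.
#' @param alpha Band significance level.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tpc_fit
#' @export
autoplot.tpc_fit <- function(object, bin_width = 2, alpha = 0.05, ...) {
  if (object$spec$family != "binomial") {
    abort("autoplot.tpc_fit() supports binomial fits.")
  }
  data <- object$data
  tr <- object$spec$treatment
  grid <- seq(min(data$temperature), max(data$temperature), length.out = 200)
  levs <- if (!is.null(tr)) object$xlev[[tr]] else "all"
  curves <- purrr::map_dfr(levs, function(lev) {
    dplyr::mutate(
      predict_tpc(object, grid,
                  treatment_level = if (!is.null(tr)) lev else NULL,
                  alpha = alpha),
      arm = lev)
  })
  pts <- data |>
    dplyr::mutate(
      bin = bin_width * round(.data$temperature / bin_width),
      arm = if (!is.null(tr)) as.character(.data[[tr]]) else "all"
    ) |>
    dplyr::group_by(.data$bin, .data$arm) |>
    dplyr::summarise(rate = mean(.data[[object$spec$response]]),
                     n = dplyr::n(), .groups = "drop")

  ggplot2::ggplot(curves, ggplot2::aes(x = .data$temperature, colour = .data$arm,
                                       fill = .data$arm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$lo, 0),
                                      ymax = pmin(.data$hi, 1)),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_hat), linewidth = 0.8) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$bin, y = .data$rate,
                                     size = .data$n), alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "Temperature (°C)", y = "P(success)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
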