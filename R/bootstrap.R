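#' Parametric bootstrap uncertainty for T_optimal and TPC breadth
#'
#' The optimal temperature is a nonlinear function of the fitted coefficients
#' and breadth a functional of the whole confidence band, so their sampling
#' uncertainty is obtained by parametric bootstrap: simulate `B` datasets from
#' the fitted model (redrawing random intercepts from their estimated
#' variances when the model has them), refit the same spec, and take
#' percentile intervals of the replicate `t_optimal` and breadth values.
#'
#' Replicates whose refit fails (non-convergence, separation, or a
#' non-unimodal curve) are discarded; if more than 10% fail the procedure
#' stops with an instability error reporting the count. The RNG seed is
#' recorded in the output and identical seeds give identical summaries.
#'
#' @param data Trial records.
#' @param spec A quadratic [tpc_model_spec()].
#' @param B Number of bootstrap replicates (>= 200).
#' @param seed Integer seed; required, so results are reproducible.
#' @param alpha Significance level for the percentile intervals and the
#'   breadth band (default 0.05).
#' @param grid Optional temperature grid for breadth (see [tpc_breadth()]).
#' @param treatment_level Optional treatment arm to summarise.
#' @return One-row tibble: `t_optimal`, `t_optimal_lo`, `t_optimal_hi`,
#'   `breadth`, `breadth_lo`, `breadth_hi`, `alpha`, `B`, `n_failed`, `seed`.
#' @export
bootstrap_summary <- function(data, spec, B = 500, seed, alpha = 0.05,
                              grid = NULL, treatment_level = NULL) {
  if (B < 200) abort("`B` must be at least 200 for stable percentile intervals.")
  if (missing(seed)) abort("`seed` is required for a reproducible bootstrap.")
  base <- fit_tpc(data, spec, quiet = TRUE)
  if (!base$converged) abort("The base fit did not converge; cannot bootstrap.")
  base_opt <- t_optimal(base, treatment_level)
  base_breadth <- suppressWarnings(
    tpc_breadth(base, grid = grid, alpha = alpha,
                treatment_level = treatment_level))

  reps <- withr::with_seed(seed, {
    purrr::map(seq_len(B), function(b) {
      sim <- simulate_from_fit(base)
      tryCatch({
        f <- fit_tpc(sim, spec, quiet = TRUE)
        to <- t_optimal(f, treatment_level)
        br <- suppressWarnings(
          tpc_breadth(f, grid = grid, alpha = alpha,
                      treatment_level = treatment_level))
        c(t_optimal = to, breadth = br$breadth)
      }, error = function(e) NULL)
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.1 * B) {
    abort(sprintf("Bootstrap instability: %d of %d refits failed (> 10%%).",
                  n_failed, B))
  }
  mat <- do.call(rbind, reps[ok])
  qs <- function(x) unname(stats::quantile(x, c(alpha / 2, 1 - alpha / 2),
                                           type = 7))
  ci_opt <- qs(mat[, "t_optimal"])
  ci_br <- qs(mat[, "breadth"])
  tibble(
    t_optimal = base_opt, t_optimal_lo = ci_opt[1], t_optimal_hi = ci_opt[2],
    breadth = base_breadth$breadth, breadth_lo = ci_br[1],
    breadth_hi = ci_br[2],
    alpha = alpha, B = B, n_failed = n_failed, seed = seed
  )
}

# One parametric-bootstrap dataset from a fitted model. Uses the current RNG
# stream (callers control seeding).
simulate_from_fit <- function(fit) {
  data <- fit$data
  spec <- fit$spec
  if (spec$family == "gaussian") {
    sigma <- sqrt(sum(stats::residuals(fit$model)^2) / fit$n)  # MLE sigma
    data[[spec$response]] <- stats::fitted(fit$model) + rnorm(fit$n, 0, sigma)
    return(data)
  }
  if (length(spec$random) == 0) {
    p <- stats::fitted(fit$model)
  } else {
    X <- lme4::getME(fit$model, "X")
    eta <- drop(X %*% fit$coefficients)
    for (g in spec$random) {
      lev <- levels(data[[g]])
      sd_g <- sqrt(fit$re_variances[[g]])
      u <- rnorm(length(lev), 0, sd_g)
      eta <- eta + u[as.integer(data[[g]])]
    }
    p <- plogis(eta)
  }
  data[[spec$response]] <- rbinom(fit$n, 1, p)
  data
}
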