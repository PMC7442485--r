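#' Run the simulate / fit / theory pipeline from a config
#'
#' Executes an end-to-end analysis described by a single structured config
#' (YAML or JSON file, or an equivalent named list) and writes its artifacts
#' to `out_dir`: simulated trial records with a ground-truth sidecar, a JSON
#' fit report (coefficients, covariance, random-effect variances,
#' log-likelihood, tests, optimum/breadth summaries), fitted-curve CSVs with
#' confidence bands, theory curves, and a plain-text log recording the package
#' version, seed and config hash. Reruns with identical config and seed are
#' reproducible.
#'
#' The config has top-level fields `mode` (`"simulate"`, `"fit"`, `"theory"`
#' or `"run"`), `seed`, and mode-specific blocks:
#' * `simulate`: either `lab: {t_opt, p_max, h, n_per_temp, temps}` or
#'   `field: {design: {...}, treatment_var, arms: {<arm>: {t_opt, p_max, h}}}`.
#' * `input`: `path` to a trials CSV and optional `mapping`/`recode` blocks
#'   (used by `fit` when no simulation block is present).
#' * `model`: `degree`, optional `treatment`, `interaction`, `random`,
#'   `bootstrap_B`.
#' * `theory`: `focal`/`competitor` TPC parameter triples and `variance_v`.
#'
#' @param config Path to a YAML/JSON config file, or a named list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- load_config(config)
  mode <- cfg$mode %||% "run"
  if (!mode %in% c("simulate", "fit", "theory", "run")) {
    abort(sprintf("Unknown pipeline mode `%s`.", mode))
  }
  seed <- as.integer(cfg$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log_lines <- c(
    sprintf("tpcniche %s", as.character(packageVersion("tpcniche"))),
    sprintf("mode: %s", mode),
    sprintf("seed: %d", seed),
    sprintf("config_hash: %s", rlang::hash(cfg)),
    sprintf("started: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )

  records <- NULL
  if (mode %in% c("simulate", "run") || (!is.null(cfg$simulate) && mode == "fit")) {
    sim <- simulate_from_config(cfg$simulate, seed)
    records <- sim$records
    paths$trials <- file.path(out_dir, "trials.csv")
    write_trials(records, paths$trials)
    paths$truth <- file.path(out_dir, "truth.json")
    jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    log_lines <- c(log_lines, sprintf("simulated records: %d", nrow(records)))
  }

  if (mode %in% c("fit", "run")) {
    if (is.null(records)) {
      if (is.null(cfg$input$path)) abort("`fit` needs an `input: path:` block or a `simulate` block.")
      mapping <- config_mapping(cfg$input)
      records <- read_trials(cfg$input$path, mapping, quiet = TRUE)
      log_lines <- c(log_lines, sprintf("read records: %d from %s",
                                        nrow(records), cfg$input$path))
    }
    fit_out <- fit_from_config(records, cfg$model %||% list(), seed)
    paths$report <- file.path(out_dir, "report.json")
    jsonlite::write_json(fit_out$report, paths$report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths$fitted_curve <- file.path(out_dir, "fitted_curve.csv")
    readr::write_csv(fit_out$curve, paths$fitted_curve)
    log_lines <- c(log_lines, sprintf("fitted: %s, n = %d",
                                      fit_out$report$model$family,
                                      fit_out$report$model$n))
  }

  if (mode %in% c("theory", "run") && !is.null(cfg$theory)) {
    th <- theory_from_config(cfg$theory)
    paths$theory_curve <- file.path(out_dir, "theory_curve.csv")
    readr::write_csv(th$curve, paths$theory_curve)
    paths$theory_summary <- file.path(out_dir, "theory_summary.json")
    jsonlite::write_json(th$summary, paths$theory_summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    log_lines <- c(log_lines, "theory curves written")
  }

  paths$log <- file.path(out_dir, "run.log")
  writeLines(c(log_lines, sprintf("finished: %s",
                                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             paths$log)
  invisible(paths)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("Config file not found: %s", config))
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      return(jsonlite::read_json(config, simplifyVector = TRUE))
    }
    return(yaml::read_yaml(config))
  }
  if (!is.list(config)) abort("`config` must be a file path or a named list.")
  config
}

config_mapping <- function(input) {
  if (is.null(input$mapping) && is.null(input$recode)) return(NULL)
  rc <- purrr::map(input$recode %||% list(), function(x) unlist(x))
  do.call(column_mapping, c(input$mapping %||% list(), list(recode = rc)))
}

config_truth <- function(x) {
  if (!is.null(x$beta0)) {
    true_tpc_params(x$beta0, x$beta1, x$beta2)
  } else {
    coeffs_from_shape(t_opt = x$t_opt, p_max = x$p_max %||% 0.7,
                      h = x$h %||% 4.7)
  }
}

truth_json <- function(truth) {
  list(beta0 = truth$beta0, beta1 = truth$beta1, beta2 = truth$beta2,
       t_optimal = truth$t_optimal, p_max = truth$p_max)
}

simulate_from_config <- function(sim, seed) {
  if (is.null(sim)) abort("Config error: no `simulate` block.")
  if (!is.null(sim$lab)) {
    truth <- config_truth(sim$lab)
    records <- simulate_lab(
      truth,
      temps = unlist(sim$lab$temps) %||% c(8, 10, 12, 16, 20, 22),
      n_per_temp = sim$lab$n_per_temp %||% 20,
      seed = seed,
      dropout_rate = sim$lab$dropout_rate %||% 0
    )
    return(list(records = records,
                truth = list(seed = seed, lab = truth_json(truth))))
  }
  if (!is.null(sim$field)) {
    dn <- sim$field$design %||% list()
    design_args <- dn[intersect(names(dn), names(formals(field_design)))]
    if (!is.null(design_args$years)) design_args$years <- unlist(design_args$years)
    if (!is.null(design_args$elevations)) design_args$elevations <- unlist(design_args$elevations)
    design <- do.call(field_design, design_args)
    arms <- purrr::map(sim$field$arms, config_truth)
    records <- simulate_field(
      design, arms,
      treatment_var = sim$field$treatment_var %||% "competition",
      seed = seed, dropout_rate = sim$field$dropout_rate %||% 0
    )
    return(list(records = records,
                truth = list(seed = seed,
                             arms = purrr::map(arms, truth_json),
                             sigma_plot = design$sigma_plot,
                             sigma_year = design$sigma_year)))
  }
  abort("Config error: `simulate` needs a `lab` or `field` block.")
}

fit_from_config <- function(records, model, seed) {
  spec <- tpc_model_spec(
    degree = model$degree %||% 2,
    treatment = model$treatment,
    interaction = isTRUE(model$interaction),
    random = unlist(model$random) %||% character()
  )
  fit <- fit_tpc(records, spec, quiet = TRUE)

  tests <- list()
  if (spec$degree == 2 && !spec$interaction) {
    tests$temperature <- as.list(temperature_lrt(records, spec))
  }
  if (spec$interaction) {
    cmp <- compare_tpcs(records, spec)
    attributes(cmp)[c("full", "reduced")] <- NULL
    tests$interaction <- as.list(cmp)
  }

  levels_to_report <- if (is.null(spec$treatment)) list(NULL) else
    as.list(fit$xlev[[spec$treatment]])
  summaries <- purrr::map(levels_to_report, function(lev) {
    s <- tryCatch(
      suppressWarnings(tpc_breadth(fit, treatment_level = lev)),
      error = function(e) tibble(t_optimal = NA_real_, breadth_lo = NA_real_,
                                 breadth_hi = NA_real_, breadth = NA_real_,
                                 alpha = 0.05))
    c(list(treatment_level = lev %||% "all"), as.list(s))
  })

  boot <- NULL
  if (!is.null(model$bootstrap_B)) {
    boot <- as.list(bootstrap_summary(records, spec, B = model$bootstrap_B,
                                      seed = seed))
  }

  grid <- seq(min(records$temperature), max(records$temperature), length.out = 201)
  curve <- purrr::map_dfr(levels_to_report, function(lev) {
    dplyr::mutate(predict_tpc(fit, grid, treatment_level = lev),
                  treatment_level = lev %||% "all")
  })

  report <- list(
    model = list(
      family = spec$family, formula = deparse(spec_formula(spec)), n = fit$n,
      n_dropped = fit$n_dropped, converged = fit$converged,
      coefficients = as.list(fit$coefficients),
      vcov = unname(apply(fit$vcov, 1, as.list)),
      re_variances = as.list(fit$re_variances),
      loglik = fit$loglik
    ),
    tests = tests,
    tpc_summaries = summaries,
    bootstrap = boot,
    seed = seed
  )
  list(report = report, curve = curve)
}

theory_from_config <- function(theory) {
  focal <- fundamental_tpc(theory$focal$t_opt, theory$focal$t_max,
                           theory$focal$sigma_p,
                           theory$focal$label %||% "focal")
  competitor <- fundamental_tpc(theory$competitor$t_opt, theory$competitor$t_max,
                                theory$competitor$sigma_p,
                                theory$competitor$label %||% "competitor")
  v <- theory$variance_v %||% 4
  grid <- NULL
  if (!is.null(theory$grid)) {
    grid <- seq(theory$grid$from, theory$grid$to, by = theory$grid$by %||% 0.05)
  }
  rt_f <- realized_tpc(focal, competitor, v, grid)
  rt_c <- realized_tpc(competitor, focal, v, grid)
  curve <- dplyr::mutate(rt_f$curve,
                         ratio_competitor = rt_c$curve$ratio)
  fsum <- function(tpc) {
    fc <- fundamental_curve(tpc)
    as.list(curve_summary(fc$temperature, fc$performance))
  }
  rsum <- function(rt) {
    list(t_optimal = rt$t_optimal,
         width_interval = as.list(setNames(rt$width_interval, c("lo", "hi"))),
         width = rt$width)
  }
  summary <- list(
    variance_v = v,
    fundamental = list(focal = fsum(focal), competitor = fsum(competitor)),
    realized = list(focal = rsum(rt_f), competitor = rsum(rt_c))
  )
  list(curve = curve, summary = summary)
}
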