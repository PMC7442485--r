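#' Specify a thermal-performance regression model
#'
#' Builds the model specification used throughout the inference pipeline: a
#' binomial (logit) or Gaussian regression of an outcome on temperature, with
#' an optional quadratic temperature term, an optional treatment factor with
#' or without treatment-by-temperature interactions, and optional random
#' intercepts (e.g. field plot and year).
#'
#' @param response Name of the response column (`"outcome"` for binary
#'   success, or e.g. `"response_value"` for Gaussian responses).
#' @param degree Polynomial degree in temperature: 0 (intercept only), 1
#'   (linear) or 2 (quadratic; the TPC model).
#' @param treatment Optional name of a treatment factor column (e.g.
#'   `"competition"` or `"group_size"`).
#' @param interaction If `TRUE`, include treatment-by-temperature interactions
#'   (`treatment:T` and, when `degree == 2`, `treatment:T^2`). Requires
#'   `treatment`.
#' @param random Character vector of grouping columns entered as independent
#'   random intercepts (e.g. `c("plot_id", "year")`); empty for a plain GLM/LM.
#' @param family `"binomial"` (logit link) or `"gaussian"` (identity link).
#'
#' @return An object of class `tpc_model_spec`.
#' @examples
#' tpc_model_spec()                                   # quadratic logistic GLM
#' tpc_model_spec(random = c("plot_id", "year"))      # field GLMM
#' tpc_model_spec(treatment = "group_size", interaction = TRUE,
#'                random = "plot_id")
#' @export
tpc_model_spec <- function(response = "outcome", degree = 2, treatment = NULL,
                           interaction = FALSE, random = character(),
                           family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  if (!degree %in% 0:2) abort("`degree` must be 0, 1 or 2.")
  if (interaction && is.null(treatment)) {
    abort("`interaction = TRUE` requires a `treatment` factor (interactions need their main effects).")
  }
  if (interaction && degree < 1) {
    abort("Treatment-by-temperature interactions require `degree >= 1`.")
  }
  structure(
    list(response = response, degree = as.integer(degree),
         treatment = treatment, interaction = isTRUE(interaction),
         random = as.character(random), family = family),
    class = "tpc_model_spec"
  )
}

#' @export
print.tpc_model_spec <- function(x, ...) {
  cat("<tpc_model_spec> ", deparse(spec_formula(x)), " [", x$family, "]\n",
      sep = "")
  invisible(x)
}

# Fixed-effect term labels, in order; used for nesting checks and df counts.
spec_fixed_terms <- function(spec) {
  terms <- character()
  if (spec$degree >= 1) terms <- c(terms, "temperature")
  if (spec$degree >= 2) terms <- c(terms, "I(temperature^2)")
  if (!is.null(spec$treatment)) terms <- c(terms, spec$treatment)
  if (spec$interaction) {
    terms <- c(terms, paste0(spec$treatment, ":temperature"))
    if (spec$degree >= 2) {
      terms <- c(terms, paste0(spec$treatment, ":I(temperature^2)"))
    }
  }
  terms
}

spec_formula <- function(spec) {
  rhs <- spec_fixed_terms(spec)
  if (length(rhs) == 0) rhs <- "1"
  if (length(spec$random) > 0) {
    rhs <- c(rhs, sprintf("(1 | %s)", spec$random))
  }
  as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")),
             env = globalenv())
}

# spec_b nested in spec_a? (same response/family/random structure, fixed
# terms a superset)
spec_nested <- function(full, reduced) {
  identical(full$response, reduced$response) &&
    identical(full$family, reduced$family) &&
    setequal(full$random, reduced$random) &&
    all(spec_fixed_terms(reduced) %in% spec_fixed_terms(full))
}
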