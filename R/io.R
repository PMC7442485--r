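#' Map source-file columns onto the canonical trial-record schema
#'
#' Field datasets arrive with arbitrary column names and outcome encodings; a
#' column mapping binds them to the canonical schema (`temperature`,
#' `outcome`, `plot_id`, `year`, `competition`, `group_size`, `elevation`,
#' `response_value`) without code changes. Value recodings translate e.g.
#' `"success"/"failure"` strings to 0/1 and must cover every observed value.
#'
#' @param ... Named canonical-field = source-column pairs, e.g.
#'   `temperature = "mean_daily_temp"`. Unmapped canonical fields are taken
#'   from identically named source columns when present.
#' @param recode Named list of recodings: each element is a named vector whose
#'   names are source values and whose values are replacements, e.g.
#'   `list(outcome = c(success = 1, failure = 0))`.
#' @param temperature_unit Must be `"C"`; the schema is Celsius-only.
#' @return An object of class `column_mapping`.
#' @export
column_mapping <- function(..., recode = list(), temperature_unit = "C") {
  if (!identical(temperature_unit, "C")) {
    abort("Temperatures must be supplied in deg C (`temperature_unit = \"C\"`).")
  }
  map <- list(...)
  canonical <- trial_record_fields()
  bad <- setdiff(names(map), canonical)
  if (length(bad) > 0) {
    abort(paste0("Unknown canonical field(s): ", paste(bad, collapse = ", "), "."))
  }
  bad_rc <- setdiff(names(recode), canonical)
  if (length(bad_rc) > 0) {
    abort(paste0("Recodings for unknown field(s): ", paste(bad_rc, collapse = ", "), "."))
  }
  structure(list(map = map, recode = recode), class = "column_mapping")
}

trial_record_fields <- function() {
  c("temperature", "outcome", "plot_id", "year", "competition", "group_size",
    "elevation", "response_value")
}

#' Read trial records from a CSV file
#'
#' Reads a headered CSV, applies an optional [column_mapping()], validates the
#' canonical schema, and reports counts of records read and kept. Validation
#' is strict rather than coercive: an unmapped required column is a schema
#' error, and any row whose outcome is not binary after recoding (missing
#' outcomes, i.e. excluded trials, are allowed) is rejected with a
#' row-numbered message. Row numbers in messages count the header as row 1,
#' matching what a reader sees in the file.
#'
#' @param path Path to a CSV file with a header row.
#' @param mapping Optional [column_mapping()]; by default columns are assumed
#'   to already use canonical names.
#' @param quiet If `TRUE`, suppress the read/kept message.
#' @return A tibble of validated trial records.
#' @export
read_trials <- function(path, mapping = NULL, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  n_read <- nrow(raw)

  map <- if (is.null(mapping)) list() else mapping$map
  recode <- if (is.null(mapping)) list() else mapping$recode

  out <- tibble(.rows = n_read)
  for (field in trial_record_fields()) {
    src <- map[[field]] %||% field
    if (src %in% names(raw)) {
      out[[field]] <- raw[[src]]
    } else if (field %in% c("temperature", "outcome")) {
      abort(sprintf("Schema error: required field `%s` is not mapped to any column.", field))
    } else {
      out[[field]] <- if (field %in% c("elevation", "response_value"))
        NA_real_ else "none"
    }
  }

  for (field in names(recode)) {
    rc <- recode[[field]]
    vals <- as.character(out[[field]])
    known <- is.na(vals) | vals %in% names(rc)
    if (!all(known)) {
      rows <- which(!known)[seq_len(min(5, sum(!known)))] + 1L  # +1 for header
      abort(sprintf(
        "Validation error: field `%s` has unmapped value(s) %s at file row(s) %s.",
        field,
        paste(unique(vals[!known][1:min(3, sum(!known))]), collapse = ", "),
        paste(rows, collapse = ", ")))
    }
    new <- rep(NA_character_, length(vals))
    new[!is.na(vals)] <- unname(rc[vals[!is.na(vals)]])
    out[[field]] <- new
  }

  out$temperature <- as.numeric(out$temperature)
  if (any(!is.finite(out$temperature))) {
    rows <- which(!is.finite(out$temperature)) + 1L
    abort(sprintf("Validation error: non-finite `temperature` at file row(s) %s.",
                  paste(head(rows, 5), collapse = ", ")))
  }
  oc <- suppressWarnings(as.numeric(out$outcome))
  bad <- !is.na(out$outcome) & (is.na(oc) | !oc %in% c(0, 1))
  if (any(bad)) {
    rows <- which(bad) + 1L
    abort(sprintf("Validation error: non-binary `outcome` at file row(s) %s.",
                  paste(head(rows, 5), collapse = ", ")))
  }
  out$outcome <- as.integer(oc)
  for (f in c("plot_id", "year", "competition", "group_size")) {
    out[[f]] <- as.character(out[[f]])
  }
  out$elevation <- as.numeric(out$elevation)
  out$response_value <- as.numeric(out$response_value)

  if (!quiet) {
    inform(sprintf("Read %d record(s); kept %d (%d with missing outcome).",
                   n_read, nrow(out), sum(is.na(out$outcome))))
  }
  out
}

#' Write trial records to CSV
#'
#' @param records A tibble of trial records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}
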