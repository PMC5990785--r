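#' @keywords internal
CONTEXTS <- c("rest", "travel", "alert")
#' @keywords internal
SEXES <- c("female", "male")
#' @keywords internal
AGE_CLASSES <- c("adult", "subadult")
#' @keywords internal
OBSERVERS <- c("CC", "TG")
#' @keywords internal
DEVICES <- c("s", "cs", "c")

# tolerance for cross-checking derived fields (f0 drop, positions) against
# values stored in a file, in the variable's own units
DERIVED_TOL <- 1e-6

#' Canonical call-table columns
#'
#' Column names, in canonical order, of a call table: one row per measured
#' call, holding identity and recording covariates plus the acoustic
#' variables (durations and times in seconds, frequencies in Hz, positions
#' as proportions of call duration).
#'
#' @return Character vector of column names.
#' @export
call_table_columns <- function() {
  c("call_id", "subject_id", "sex", "age_years", "age_class", "context",
    "observer", "device", "bout_id", "position_in_bout",
    "duration_s", "f0_start_hz", "f0_end_hz", "f0_max_hz", "f0_drop_hz",
    "slope_steepness_hz_per_s", "peak_freq_hz", "t_f0max_s", "t_peakfreq_s",
    "pos_f0max", "pos_peakfreq", "inter_call_interval_s")
}

#' Acoustic candidate variables for screening
#'
#' The nine acoustic predictors entered into collinearity screening: call
#' duration, start/end/maximum F0, F0 drop, slope steepness, the positions
#' of maximum F0 and of peak frequency (proportions of call duration), and
#' the inter-call interval. Peak frequency in Hz is measured and stored but
#' serves only to derive its position, so it is not a screening candidate.
#'
#' @return Character vector of variable names.
#' @export
candidate_variables <- function() {
  c("duration_s", "f0_start_hz", "f0_end_hz", "f0_max_hz", "f0_drop_hz",
    "slope_steepness_hz_per_s", "pos_f0max", "pos_peakfreq",
    "inter_call_interval_s")
}

#' The six retained analysis variables
#'
#' The variable set surviving screening at the default thresholds: call
#' duration, maximum F0, F0 drop, position of peak frequency, position of
#' maximum F0 and inter-call interval.
#'
#' @return Character vector of variable names.
#' @export
analysis_variables <- function() {
  c("duration_s", "f0_max_hz", "f0_drop_hz", "pos_peakfreq", "pos_f0max",
    "inter_call_interval_s")
}

stop_rows <- function(msg, rows) {
  stop(sprintf("%s (row%s %s)", msg, if (length(rows) > 1) "s" else "",
               paste(utils::head(rows, 10L), collapse = ", ")), call. = FALSE)
}

#' Validate a call table
#'
#' Checks column presence, closed categorical sets, positivity constraints
#' and the derived-field invariants: \code{f0_drop_hz = f0_max_hz -
#' f0_end_hz}, \code{pos_f0max = t_f0max_s / duration_s},
#' \code{pos_peakfreq = t_peakfreq_s / duration_s}, and
#' \code{f0_max_hz >= f0_start_hz, f0_end_hz}. Violations are reported with
#' the offending row numbers.
#'
#' @param tab A data frame with the columns of \code{\link{call_table_columns}}.
#' @return The validated table, invisibly classed as \code{call_table}.
#' @export
validate_call_table <- function(tab) {
  missing_cols <- setdiff(call_table_columns(), names(tab))
  if (length(missing_cols) > 0)
    stop("call table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  chk_set <- function(col, set) {
    bad <- which(!(tab[[col]] %in% set))
    if (length(bad) > 0)
      stop_rows(sprintf("column '%s' outside {%s}", col,
                        paste(set, collapse = ", ")), bad)
  }
  chk_set("sex", SEXES)
  chk_set("age_class", AGE_CLASSES)
  chk_set("context", CONTEXTS)
  chk_set("observer", OBSERVERS)
  chk_set("device", DEVICES)

  chk_pos <- function(col, strict = TRUE, allow_na = FALSE) {
    x <- tab[[col]]
    bad <- if (strict) which(!is.na(x) & x <= 0) else which(!is.na(x) & x < 0)
    if (!allow_na) bad <- sort(unique(c(bad, which(is.na(x)))))
    if (length(bad) > 0)
      stop_rows(sprintf("column '%s' must be %s%s", col,
                        if (strict) "> 0" else ">= 0",
                        if (allow_na) " where present" else ""), bad)
  }
  chk_pos("duration_s")
  chk_pos("f0_start_hz"); chk_pos("f0_end_hz"); chk_pos("f0_max_hz")
  chk_pos("f0_drop_hz", strict = FALSE)
  chk_pos("peak_freq_hz")
  chk_pos("age_years", strict = FALSE)
  chk_pos("inter_call_interval_s", strict = TRUE, allow_na = TRUE)
  chk_pos("position_in_bout")

  bad <- which(abs(tab$f0_drop_hz - (tab$f0_max_hz - tab$f0_end_hz)) > DERIVED_TOL)
  if (length(bad) > 0)
    stop_rows("f0_drop_hz inconsistent with f0_max_hz - f0_end_hz", bad)
  bad <- which(tab$f0_max_hz + DERIVED_TOL < pmax(tab$f0_start_hz, tab$f0_end_hz))
  if (length(bad) > 0)
    stop_rows("f0_max_hz below f0_start_hz or f0_end_hz", bad)
  for (v in c("f0max", "peakfreq")) {
    tcol <- sprintf("t_%s_s", v); pcol <- sprintf("pos_%s", v)
    bad <- which(tab[[tcol]] < -DERIVED_TOL |
                 tab[[tcol]] > tab$duration_s + DERIVED_TOL)
    if (length(bad) > 0)
      stop_rows(sprintf("column '%s' outside [0, duration_s]", tcol), bad)
    bad <- which(abs(tab[[pcol]] - tab[[tcol]] / tab$duration_s) > DERIVED_TOL)
    if (length(bad) > 0)
      stop_rows(sprintf("column '%s' inconsistent with %s / duration_s",
                        pcol, tcol), bad)
  }

  class(tab) <- unique(c("call_table", class(tab)))
  invisible(tab)
}

#' Read a call table from CSV
#'
#' Reads a comma-separated call table (header row, UTF-8, "." decimal;
#' missing inter-call interval encoded as an empty field), optionally
#' renaming file columns to the canonical names, and validates it. Derived
#' fields present in the file are cross-checked against their definitions.
#'
#' @param path Path to a CSV file.
#' @param dialect Optional named character vector mapping file column names
#'   to canonical names, e.g. \code{c(id = "call_id")}.
#' @return A \code{call_table} data frame.
#' @export
read_call_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (!is.null(dialect)) {
    hit <- names(tab) %in% names(dialect)
    names(tab)[hit] <- unname(dialect[names(tab)[hit]])
  }
  for (col in c("call_id", "subject_id", "bout_id"))
    if (col %in% names(tab)) tab[[col]] <- as.character(tab[[col]])
  tab <- validate_call_table(tab)
  tab[, call_table_columns(), drop = FALSE]
}

#' Write a call table to CSV
#'
#' Inverse of \code{\link{read_call_table}}; absent inter-call intervals are
#' written as empty fields. Numeric fields are written at full double
#' precision so the round trip is lossless.
#'
#' @param tab A \code{call_table} data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_call_table <- function(tab, path) {
  utils::write.csv(tab[, call_table_columns(), drop = FALSE], path,
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
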