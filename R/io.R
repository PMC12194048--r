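#' Read a daily series from CSV
#'
#' Expects one row per day with an ISO date column and a numeric value
#' column.  The method assumes a complete equally spaced series: calendar
#' gaps, duplicated dates, missing or non-numeric values are hard errors
#' reported with their row numbers, never imputed.
#'
#' @param path CSV file path.
#' @param date_column,value_column Column names (defaults `"date"`,
#'   `"value"`).
#'
#' @return A [regular_series()] anchored at the first date.
#' @export
read_series <- function(path, date_column = "date", value_column = "value") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(date_column, value_column))
    if (!col %in% names(df)) stop("column '", col, "' not found in ", path)
  dates <- as.Date(df[[date_column]])
  vals <- df[[value_column]]
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(as.numeric(vals))))
    stop("non-numeric values at rows: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (anyNA(dates))
    stop("unparseable dates at rows: ",
         paste(utils::head(which(is.na(dates)), 5), collapse = ", "))
  if (anyNA(vals))
    stop("missing values at rows: ",
         paste(utils::head(which(is.na(vals)), 5), collapse = ", "),
         " (the method assumes a complete series)")
  d <- diff(as.integer(dates))
  if (any(d == 0))
    stop("duplicated dates at rows: ",
         paste(utils::head(which(d == 0) + 1L, 5), collapse = ", "))
  if (any(d != 1))
    stop("calendar gap before rows: ",
         paste(utils::head(which(d != 1) + 1L, 5), collapse = ", "),
         " (series must be daily with no gaps)")
  regular_series(vals, start = dates[1L])
}

#' Write a series to CSV
#'
#' Columns `date,value` (plus `valid` when the series carries an eroded
#' filter mask); invalid positions have empty values.
#'
#' @param x A [regular_series()] or `pc_component`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  x <- as_regular_series(x)
  n <- length(x$values)
  dates <- if (is.null(x$start)) seq_len(n) - 1L else x$start + (seq_len(n) - 1L)
  df <- data.frame(date = dates, value = x$values)
  if (!all(x$valid)) df$valid <- x$valid
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# English day names for a Date, independent of locale
# (1970-01-01 is a Thursday).
weekday_name <- function(d) {
  days <- c("Sunday", "Monday", "Tuesday", "Wednesday",
            "Thursday", "Friday", "Saturday")
  days[(as.integer(d) + 4L) %% 7L + 1L]
}

# Human-readable phase labels for a band: weekday names for p = 7,
# month-day of the anchor cycle otherwise, plain phase index when
# no calendar anchor exists.
phase_labels <- function(band) {
  if (is.null(band$anchor)) return(as.character(band$phase_index))
  dates <- band$anchor + band$phase_index
  if (band$p == 7L) weekday_name(dates) else format(dates, "%b-%d")
}

#' Write a confidence band to CSV
#'
#' Columns `phase_index, anchor_label, lower, point_estimate, upper`;
#' exactly `p` data rows.  Labels are weekday names for weekly bands and
#' month-day labels otherwise.
#'
#' @param band A `ci_band`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_band <- function(band, path) {
  stopifnot(inherits(band, "ci_band"))
  df <- data.frame(phase_index = band$phase_index,
                   anchor_label = phase_labels(band),
                   lower = band$lower,
                   point_estimate = band$point_estimate,
                   upper = band$upper)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the component summary table as TSV
#'
#' @param tbl Output of [summary_table()] (or an empty data.frame for a
#'   header-only file).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(tbl, path) {
  cols <- c("label", "period", "frequency", "upper_min", "upper_max",
            "lower_min", "lower_max", "significant")
  if (nrow(tbl) == 0L)
    tbl <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))),
                           cols)
  utils::write.table(tbl[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a plain-text run log
#'
#' Records every run parameter (one `key: value` line each) so any
#' output can be regenerated from the input and this log.
#'
#' @param params Named list of parameters (vectors are comma-joined).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_log <- function(params, path) {
  stopifnot(is.list(params), !is.null(names(params)))
  lines <- vapply(names(params), function(nm) {
    sprintf("%s: %s", nm, paste(as.character(params[[nm]]), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' Sidecar for [simulate_series()] output: maps each period to its exact
#' phase-mean vector.
#'
#' @param ground_truth The `ground_truth` element of [simulate_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, digits = NA)
  invisible(path)
}
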