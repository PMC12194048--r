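#' Regularly sampled univariate time series
#'
#' Light-weight container for an equally spaced series sampled once per
#' step (one day for calendar-anchored data).  Filtered products carry a
#' logical validity mask: positions where a centred filter window does not
#' fit are `NA` in `values` and `FALSE` in `valid`.
#'
#' @param values Numeric vector of observations (all finite unless masked).
#' @param start Optional calendar anchor for the first observation, a
#'   `Date` (or something coercible).  `NULL` for index-anchored series.
#' @param valid Optional logical vector, same length as `values`, marking
#'   positions that hold a usable observation.  Defaults to all `TRUE`.
#'   The valid region must be a single contiguous run.
#'
#' @return An object of class `"regular_series"`: a list with elements
#'   `values`, `start`, `valid`.
#' @export
#' @examples
#' x <- regular_series(sin(2 * pi * (0:27) / 7), start = as.Date("2001-01-01"))
#' x
regular_series <- function(values, start = NULL, valid = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("series must contain at least one value")
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  if (length(valid) != length(values))
    stop("`valid` must have the same length as `values`")
  if (!any(valid)) stop("series has no valid observations")
  if (anyNA(values[valid]) || any(!is.finite(values[valid])))
    stop("valid observations must all be finite")
  run <- range(which(valid))
  if (!all(valid[run[1]:run[2]]))
    stop("the valid region must be contiguous")
  if (!is.null(start)) start <- as.Date(start)
  structure(list(values = values, start = start, valid = valid),
            class = "regular_series")
}

#' @export
print.regular_series <- function(x, ...) {
  n <- length(x$values)
  nv <- sum(x$valid)
  cat(sprintf("<regular_series> %d observations (%d valid)\n", n, nv))
  if (!is.null(x$start))
    cat(sprintf("  anchored at %s, daily step\n", format(x$start)))
  v <- valid_values(x)
  cat(sprintf("  range of valid values: [%.4g, %.4g]\n", min(v), max(v)))
  invisible(x)
}

#' @export
length.regular_series <- function(x) length(x$values)

# Coerce anything series-like to a regular_series.
as_regular_series <- function(x) {
  if (inherits(x, "regular_series")) return(x)
  if (inherits(x, "pc_component")) return(x$series)
  if (is.numeric(x)) return(regular_series(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a regular series")
}

#' Extract the contiguous run of valid observations
#'
#' Filtered series carry invalid (edge-truncated) positions; this
#' returns just the usable values, in order.
#'
#' @param x A [regular_series()], `pc_component`, or numeric vector.
#' @return Numeric vector of the valid observations.
#' @export
valid_values <- function(x) {
  x <- as_regular_series(x)
  x$values[x$valid]
}

# 1-based index of the first valid observation.
first_valid_index <- function(x) {
  x <- as_regular_series(x)
  which(x$valid)[1L]
}

# Calendar date of the first valid observation (NULL if index-anchored).
anchor_date <- function(x) {
  x <- as_regular_series(x)
  if (is.null(x$start)) return(NULL)
  x$start + (first_valid_index(x) - 1L)
}
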