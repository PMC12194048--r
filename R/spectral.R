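#' Raw FFT periodogram
#'
#' Spectral density estimate used to screen for candidate periodically
#' correlated frequencies.  The mean (and by default a linear trend) is
#' removed, then the power at Fourier frequency `j/n` is
#' `|DFT coefficient|^2 / n` for `j = 1, ..., floor(n/2)`.  No tapering
#' or smoothing is applied: peaks sit exactly at the raw periodogram
#' ordinates.
#'
#' @param x A [regular_series()] or numeric vector.
#' @param detrend Remove a least-squares linear trend before the FFT
#'   (default `TRUE`); the mean is always removed.
#'
#' @return Object of class `"periodogram"`: a data.frame with columns
#'   `frequency` (cycles/sample, strictly increasing in (0, 0.5]),
#'   `period` (= 1/frequency, samples), and `power` (amplitude^2 scale),
#'   with the series length in attribute `n`.
#' @export
#' @examples
#' x <- cos(2 * pi * (0:63) / 8)
#' pg <- periodogram(regular_series(x))
#' pg[which.max(pg$power), ]   # spike at frequency 1/8, power n/4 = 16
periodogram <- function(x, detrend = TRUE) {
  v <- valid_values(as_regular_series(x))
  n <- length(v)
  if (n < 4L) stop("periodogram needs at least 4 observations")
  if (detrend) {
    t0 <- seq_len(n)
    v <- stats::lm.fit(cbind(1, t0), v)$residuals
  } else {
    v <- v - mean(v)
  }
  d <- stats::fft(v)
  j <- seq_len(n %/% 2L)
  out <- data.frame(frequency = j / n,
                    period = n / j,
                    power = Mod(d[j + 1L])^2 / n)
  attr(out, "n") <- n
  class(out) <- c("periodogram", "data.frame")
  out
}

#' Highest-power periods, merged with user-supplied candidates
#'
#' Returns the `count` highest-power Fourier frequencies as periods,
#' merged with any externally motivated candidate periods (e.g. 7 days
#' for the workweek), each mapped to its nearest Fourier frequency for
#' the power lookup, and sorted by power.
#'
#' @param pg A [periodogram()].
#' @param count Number of top frequencies to return (>= 1).
#' @param candidate_periods Optional numeric vector of periods (samples)
#'   to include regardless of rank.
#'
#' @return data.frame with columns `period`, `frequency`, `power`,
#'   sorted by decreasing power.
#' @export
top_periods <- function(pg, count, candidate_periods = NULL) {
  stopifnot(inherits(pg, "periodogram"))
  if (nrow(pg) == 0L) stop("empty periodogram")
  if (length(count) != 1L || !is.finite(count) || count < 1)
    stop("`count` must be a positive integer")
  ord <- order(pg$power, decreasing = TRUE)
  keep <- ord[seq_len(min(count, nrow(pg)))]
  if (!is.null(candidate_periods)) {
    for (p in candidate_periods) {
      if (!is.finite(p) || p <= 0) stop("candidate periods must be positive")
      j <- which.min(abs(pg$frequency - 1 / p))
      keep <- union(keep, j)
    }
  }
  res <- pg[keep, c("period", "frequency", "power")]
  res <- res[order(res$power, decreasing = TRUE), ]
  rownames(res) <- NULL
  res
}
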