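#' Bootstrap configuration
#'
#' @param B Number of independent block-bootstrap resamples (the study
#'   standard is 1000).
#' @param alpha Two-sided level of the percentile band (0.05 gives the
#'   2.5th/97.5th percentile band).
#' @param seed Integer seed; bands are a pure function of
#'   (series, period, B, alpha, seed).
#'
#' @return Object of class `"bootstrap_config"`.
#' @export
bootstrap_config <- function(B = 1000L, alpha = 0.05, seed = 1L) {
  if (length(B) != 1L || !is.finite(B) || B < 1 || B != round(B))
    stop("`B` must be a positive integer")
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly between 0 and 1")
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("`seed` must be an integer")
  structure(list(B = as.integer(B), alpha = alpha, seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Periodic (phase) mean of a series
#'
#' Entry `j` (0-based phase) is the mean of all valid observations at
#' positions congruent to `j` modulo `p`, phases counted from the first
#' valid observation.  This is the statistic that the period-aligned
#' bootstrap resamples.
#'
#' @param x A [regular_series()], `pc_component`, or numeric vector.
#' @param p Integer period, at least 2.
#'
#' @return Numeric vector of length `p`.
#' @export
#' @examples
#' periodic_mean(c(1, 2, 3, 5), 3)   # phase 0 averages 1 and 5 -> c(3, 2, 3)
periodic_mean <- function(x, p) {
  p <- check_period(p)
  v <- valid_values(x)
  phase_means_of(v, p)
}

check_period <- function(p) {
  if (length(p) != 1L || !is.finite(p) || p < 2 || p != round(p))
    stop("`p` must be an integer period >= 2")
  as.integer(p)
}

# Valid values arranged as a p x ncycles matrix, partial last cycle
# dropped.  Column r holds the cycle starting at phase-0 position r*p.
cycle_matrix <- function(x, p) {
  v <- valid_values(x)
  ncyc <- length(v) %/% p
  if (ncyc < 2L)
    stop("need at least two complete cycles of period ", p,
         " (have ", length(v), " valid points)")
  matrix(v[seq_len(ncyc * p)], nrow = p)
}

#' One GSBB resample of a period-aligned series
#'
#' Draws a generalized seasonal block bootstrap resample with block
#' length equal to the period `p`: the resample is a concatenation of
#' whole cycles, each copied from a uniformly chosen phase-0 block start
#' `r*p` of the input.  Every output position therefore originates from
#' an input position with the same phase.  The trailing partial cycle of
#' the input (when the valid length is not a multiple of `p`) is dropped
#' before resampling so all blocks are full length.
#'
#' Uses the current RNG state; seed externally (or via
#' [bootstrap_band()]) for reproducibility.
#'
#' @param x A [regular_series()], `pc_component`, or numeric vector with
#'   at least two complete cycles of valid data.
#' @param p Integer period (= block length), at least 2.
#'
#' @return Numeric vector of length `floor(n_valid/p) * p`, with the
#'   0-based source indices (into the valid region) in attribute
#'   `source_index`.
#' @export
gsbb_resample <- function(x, p) {
  p <- check_period(p)
  M <- cycle_matrix(x, p)
  ncyc <- ncol(M)
  r <- sample.int(ncyc, ncyc, replace = TRUE)
  out <- as.vector(M[, r])
  attr(out, "source_index") <- rep((r - 1L) * p, each = p) + 0:(p - 1L)
  out
}

#' Percentile confidence band for the periodic mean
#'
#' For `b = 1, ..., B` draws a GSBB resample and computes its periodic
#' mean; the band's lower/upper curves are the phase-wise empirical
#' `alpha/2` and `1 - alpha/2` quantiles (type-7, the inclusive
#' linear-interpolation convention) of those `B` periodic means.  The
#' point estimate is the periodic mean of the input itself.
#'
#' Internally the periodic mean of a resample is computed as the row
#' means of the selected cycle columns, which is algebraically identical
#' to `periodic_mean(gsbb_resample(x, p), p)` with the same draws.
#'
#' @param x A [regular_series()], `pc_component`, or numeric vector.
#' @param p Integer period, at least 2.
#' @param cfg A [bootstrap_config()].
#'
#' @return Object of class `"ci_band"`: list with `p`, `phase_index`
#'   (0-based), `lower`, `upper`, `point_estimate` (all length `p`),
#'   `alpha`, `B`, `ncycles` used, and the calendar `anchor` of phase 0
#'   (date of the first valid observation; `NULL` if index-anchored).
#' @export
bootstrap_band <- function(x, p, cfg) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  p <- check_period(p)
  M <- cycle_matrix(x, p)
  ncyc <- ncol(M)
  set.seed(cfg$seed)
  boot_means <- matrix(NA_real_, nrow = p, ncol = cfg$B)
  for (b in seq_len(cfg$B)) {
    r <- sample.int(ncyc, ncyc, replace = TRUE)
    boot_means[, b] <- rowMeans(M[, r, drop = FALSE])
  }
  probs <- c(cfg$alpha / 2, 1 - cfg$alpha / 2)
  qs <- apply(boot_means, 1L, stats::quantile, probs = probs,
              type = 7, names = FALSE)
  anchor <- if (is.numeric(x)) NULL else anchor_date(x)
  new_ci_band(p = p, lower = qs[1L, ], upper = qs[2L, ],
              point_estimate = periodic_mean(x, p),
              alpha = cfg$alpha, B = cfg$B, ncycles = ncyc, anchor = anchor)
}

new_ci_band <- function(p, lower, upper, point_estimate, alpha, B,
                        ncycles, anchor = NULL) {
  stopifnot(length(lower) == p, length(upper) == p,
            length(point_estimate) == p, all(lower <= upper + 1e-12))
  structure(list(p = as.integer(p), phase_index = 0:(p - 1L),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 point_estimate = as.numeric(point_estimate),
                 alpha = alpha, B = as.integer(B),
                 ncycles = as.integer(ncycles), anchor = anchor),
            class = "ci_band")
}

#' @export
print.ci_band <- function(x, ...) {
  cat(sprintf(
    "<ci_band> period p = %d, %d%% percentile band from B = %d resamples (%d cycles)\n",
    x$p, round(100 * (1 - x$alpha)), x$B, x$ncycles))
  cat(sprintf("  upper bound range: (%.4g, %.4g)\n", min(x$upper), max(x$upper)))
  cat(sprintf("  lower bound range: (%.4g, %.4g)\n", min(x$lower), max(x$lower)))
  if (!is.null(x$anchor))
    cat(sprintf("  phase 0 anchored at %s\n", format(x$anchor)))
  invisible(x)
}

# Band width per phase.
band_width <- function(band) band$upper - band$lower
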