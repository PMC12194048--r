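#' Plan for one periodically correlated component
#'
#' Bundles the label, centre frequency, bootstrap period, and KZFT
#' window for one component of interest.  The bootstrap period defaults
#' to `round(1/nu)`; harmonics of an annual cycle use the conventional
#' integer discretizations (183 for 2/365, 122 for 3/365).  The window
#' defaults to three times the period, rounded up to the next odd
#' integer.
#'
#' @param label Short name for the component (e.g. `"weekly"`).
#' @param period Bootstrap period in samples; either `period` or `nu`
#'   must be given.
#' @param nu Centre frequency in cycles/sample; defaults to `1/period`.
#' @param m Odd KZFT window length; default `next_odd(3 * period)`.
#' @param k KZFT iterations (default 1).
#'
#' @return Object of class `"component_plan"`.
#' @export
#' @examples
#' component_plan("weekly", period = 7)            # nu = 1/7, m = 21
#' component_plan("half_annual", nu = 2/365, period = 183, m = 1095)
component_plan <- function(label, period = NULL, nu = NULL, m = NULL, k = 1L) {
  if (is.null(period) && is.null(nu))
    stop("give `period` or `nu` for plan '", label, "'")
  if (is.null(nu)) nu <- 1 / period
  if (is.null(period)) period <- round(1 / nu)
  p <- check_period(period)
  if (is.null(m)) m <- next_odd(3 * p)
  spec <- kzft_spec(m = m, k = k, nu = nu)   # validates m, k, nu
  structure(list(label = as.character(label), nu = nu, p = p,
                 m = spec$m, k = spec$k, spec = spec),
            class = "component_plan")
}

# Smallest odd integer >= x.
next_odd <- function(x) {
  v <- as.integer(ceiling(x))
  if (v %% 2L == 0L) v + 1L else v
}

#' The six standard component plans for a 16-year daily series
#'
#' Annual fundamental (1/365) with its second (2/365, period 183) and
#' third (3/365, period 122) harmonics, plus 20-day, 13-day, and weekly
#' components; windows m = 1095 for the annual family, 741 for 20 days,
#' 729 for 13 and 7 days, k = 1 throughout.
#'
#' @return Named list of [component_plan()] objects, longest period first.
#' @export
default_plans <- function() {
  plans <- list(
    component_plan("annual",      nu = 1 / 365, period = 365, m = 1095),
    component_plan("half_annual", nu = 2 / 365, period = 183, m = 1095),
    component_plan("tri_annual",  nu = 3 / 365, period = 122, m = 1095),
    component_plan("every_20d",   nu = 1 / 20,  period = 20,  m = 741),
    component_plan("every_13d",   nu = 1 / 13,  period = 13,  m = 729),
    component_plan("weekly",      nu = 1 / 7,   period = 7,   m = 729))
  stats::setNames(plans, vapply(plans, `[[`, character(1), "label"))
}

#' Deterministic per-component seed
#'
#' Components at different frequencies are bootstrapped independently;
#' each gets its own RNG seed derived from the master seed and its
#' 1-based position in the plan list, keeping runs reproducible while
#' decoupling the streams.
#'
#' @param seed Master integer seed.
#' @param i Component index (>= 1).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483647)
}

#' Run the variable bandpass periodic block bootstrap
#'
#' For each plan: bandpass-filter the (mean-centered) series at the
#' plan's frequency with the KZFT, reconstruct the real component,
#' bootstrap its periodic mean with period-aligned blocks, and apply the
#' significance rule to the resulting percentile band.  Component `i`
#' uses seed `derive_seed(cfg$seed, i)`.
#'
#' @param x A [regular_series()].
#' @param plans List of [component_plan()] objects (may be empty).
#' @param cfg A [bootstrap_config()].
#' @param center Subtract the mean of the valid observations before
#'   filtering (default `TRUE`); keeps bands on a scale comparable to a
#'   zero periodic mean.
#'
#' @return Named list (by plan label); each element has `component`
#'   (a `pc_component`), `band` (a `ci_band`), `summary`
#'   (a `significance_summary`), and the `plan`.
#' @export
run_vbpbb <- function(x, plans, cfg, center = TRUE) {
  x <- as_regular_series(x)
  stopifnot(inherits(cfg, "bootstrap_config"))
  if (inherits(plans, "component_plan")) plans <- list(plans)
  out <- list()
  if (length(plans) == 0L) return(out)
  if (center) {
    mu <- mean(valid_values(x))
    x <- regular_series(x$values - mu, start = x$start, valid = x$valid)
  }
  for (i in seq_along(plans)) {
    plan <- plans[[i]]
    stopifnot(inherits(plan, "component_plan"))
    comp <- reconstruct(apply_kzft(x, plan$spec), p = plan$p)
    if (sum(comp$valid) < 2L * plan$p)
      stop("plan '", plan$label, "': filter support leaves ",
           sum(comp$valid), " valid points, fewer than two cycles of p = ",
           plan$p)
    cfg_i <- bootstrap_config(B = cfg$B, alpha = cfg$alpha,
                              seed = derive_seed(cfg$seed, i))
    band <- bootstrap_band(comp, plan$p, cfg_i)
    out[[plan$label]] <- list(plan = plan, component = comp, band = band,
                              summary = significance(band))
  }
  out
}

#' Significance of a periodic mean band
#'
#' A component is significant when its band excludes every flat
#' (constant) periodic mean: operationally, when zero lies strictly
#' inside the range over phases of the band's upper bound AND strictly
#' inside the range of its lower bound.  A band whose upper curve stays
#' entirely above zero (or lower curve entirely below) is compatible
#' with a constant mean and is not significant.
#'
#' @param band A `ci_band`.
#' @return Object of class `"significance_summary"` with `upper_range`,
#'   `lower_range` (each `c(min, max)` over phases), and `significant`.
#' @export
significance <- function(band) {
  stopifnot(inherits(band, "ci_band"))
  significance_from_ranges(range(band$upper), range(band$lower))
}

#' @rdname significance
#' @param upper_range `c(min, max)` over phases of the band's upper bound.
#' @param lower_range `c(min, max)` over phases of the band's lower bound.
#' @export
significance_from_ranges <- function(upper_range, lower_range) {
  stopifnot(length(upper_range) == 2L, length(lower_range) == 2L,
            upper_range[1] <= upper_range[2],
            lower_range[1] <= lower_range[2])
  straddles <- function(r) r[1] < 0 && 0 < r[2]
  structure(list(upper_range = as.numeric(upper_range),
                 lower_range = as.numeric(lower_range),
                 significant = straddles(upper_range) &&
                               straddles(lower_range)),
            class = "significance_summary")
}

#' @export
print.significance_summary <- function(x, ...) {
  cat(sprintf("<significance_summary> upper (%.4g, %.4g), lower (%.4g, %.4g): %s\n",
              x$upper_range[1], x$upper_range[2],
              x$lower_range[1], x$lower_range[2],
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' GSBB baseline band on the unfiltered series
#'
#' The comparison baseline: the raw series (mean-centered by default, so
#' the band is on the same zero-anchored scale as filtered components)
#' is bootstrapped directly with period-aligned blocks, noise and all
#' unrelated frequencies included.
#'
#' @param x A [regular_series()].
#' @param p Integer block period.
#' @param cfg A [bootstrap_config()]; its seed is used as-is.
#' @param center Subtract the valid-region mean first (default `TRUE`).
#'
#' @return A `ci_band`.
#' @export
run_gsbb_baseline <- function(x, p, cfg, center = TRUE) {
  x <- as_regular_series(x)
  if (center) {
    mu <- mean(valid_values(x))
    x <- regular_series(x$values - mu, start = x$start, valid = x$valid)
  }
  bootstrap_band(x, p, cfg)
}

#' Compare baseline and VBPBB band widths
#'
#' The phase-wise ratio of baseline band width to VBPBB band width,
#' summarized by its median; phases where the VBPBB width is zero are
#' excluded from the median (their count is reported).
#'
#' @param baseline A `ci_band` (typically from [run_gsbb_baseline()]).
#' @param vbpbb A `ci_band` of the same period from the filtered
#'   component.
#' @param label Optional component label carried into the result.
#'
#' @return Object of class `"band_comparison"` with
#'   `median_width_ratio`, `n_zero_excluded`, `label`.
#' @export
compare_bands <- function(baseline, vbpbb, label = NULL) {
  stopifnot(inherits(baseline, "ci_band"), inherits(vbpbb, "ci_band"))
  if (baseline$p != vbpbb$p)
    stop("bands have different periods (", baseline$p, " vs ", vbpbb$p, ")")
  bw <- band_width(baseline)
  vw <- band_width(vbpbb)
  keep <- vw > 0
  if (!any(keep)) stop("all VBPBB widths are zero; ratio undefined")
  structure(list(label = label,
                 median_width_ratio = stats::median(bw[keep] / vw[keep]),
                 n_zero_excluded = sum(!keep)),
            class = "band_comparison")
}

#' @export
print.band_comparison <- function(x, ...) {
  cat(sprintf("<band_comparison>%s median baseline/VBPBB width ratio: %.3f\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$median_width_ratio))
  if (x$n_zero_excluded > 0)
    cat(sprintf("  (%d zero-width phases excluded)\n", x$n_zero_excluded))
  invisible(x)
}

#' Bootstrap band for the sum of several components
#'
#' Each component is resampled independently with its own period (the
#' components operate at different frequencies and are treated as
#' independent); in every bootstrap iteration each component's periodic
#' mean is tiled along the common valid timeline and the tiles are added
#' pointwise.  The band is the phase-wise percentile envelope of the
#' summed curves over the first `span` positions of the common window.
#'
#' @param components List of `pc_component` objects sharing a common
#'   valid time window.
#' @param cfg A [bootstrap_config()]; component `i` uses
#'   `derive_seed(cfg$seed, i)`.
#' @param span Number of positions of the combined curve to report;
#'   defaults to the least common multiple of the periods, capped at two
#'   years (730) and at the common valid length.
#'
#' @return A `ci_band` over `span` positions (its `p` is `span`).
#' @export
sum_components <- function(components, cfg, span = NULL) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  if (length(components) == 0L) stop("empty component list")
  stopifnot(all(vapply(components, inherits, logical(1), "pc_component")))
  firsts <- vapply(components, function(cp) first_valid_index(cp$series),
                   integer(1))
  lasts <- vapply(components, function(cp) max(which(cp$series$valid)),
                  integer(1))
  T0 <- max(firsts); T1 <- min(lasts)
  if (T1 < T0) stop("components share no common valid window")
  L <- T1 - T0 + 1L
  ps <- vapply(components, `[[`, integer(1), "p")
  if (is.null(span)) span <- min(Reduce(lcm_int, ps), 730L, L)
  span <- as.integer(span)
  if (span < 1L || span > L)
    stop("`span` must lie in [1, ", L, "] (common valid length)")

  total_means <- matrix(0, nrow = span, ncol = cfg$B)
  point <- numeric(span)
  t_off <- 0:(span - 1L)
  for (i in seq_along(components)) {
    cp <- components[[i]]
    M <- cycle_matrix(cp, cp$p)
    ncyc <- ncol(M)
    set.seed(derive_seed(cfg$seed, i))
    # phase of each common-timeline position within this component
    phase <- ((T0 - firsts[i]) + t_off) %% cp$p + 1L
    for (b in seq_len(cfg$B)) {
      r <- sample.int(ncyc, ncyc, replace = TRUE)
      total_means[, b] <- total_means[, b] + rowMeans(M[, r, drop = FALSE])[phase]
    }
    point <- point + periodic_mean(cp, cp$p)[phase]
  }
  probs <- c(cfg$alpha / 2, 1 - cfg$alpha / 2)
  qs <- apply(total_means, 1L, stats::quantile, probs = probs,
              type = 7, names = FALSE)
  anchors <- lapply(components, function(cp) anchor_date(cp$series))
  anchor <- if (is.null(anchors[[1L]])) NULL else
    anchors[[1L]] + (T0 - firsts[1L])
  new_ci_band(p = span, lower = qs[1L, ], upper = qs[2L, ],
              point_estimate = point, alpha = cfg$alpha, B = cfg$B,
              ncycles = L %/% max(ps), anchor = anchor)
}

lcm_int <- function(a, b) {
  gcd <- function(x, y) if (y == 0L) x else gcd(y, x %% y)
  as.integer(a / gcd(as.integer(a), as.integer(b)) * b)
}

#' Summary table of VBPBB results
#'
#' One row per component, longest period first: label, period, frequency,
#' the ranges over phases of the band's upper and lower bounds, and the
#' significance verdict.
#'
#' @param results Output of [run_vbpbb()] (nonempty).
#' @return data.frame with columns `label`, `period`, `frequency`,
#'   `upper_min`, `upper_max`, `lower_min`, `lower_max`, `significant`.
#' @export
summary_table <- function(results) {
  if (length(results) == 0L) stop("no results to summarize")
  rows <- lapply(results, function(res) {
    s <- res$summary
    data.frame(label = res$plan$label,
               period = res$plan$p,
               frequency = res$plan$nu,
               upper_min = s$upper_range[1], upper_max = s$upper_range[2],
               lower_min = s$lower_range[1], lower_max = s$lower_range[2],
               significant = s$significant)
  })
  tbl <- do.call(rbind, rows)
  tbl <- tbl[order(tbl$period, decreasing = TRUE), ]
  rownames(tbl) <- NULL
  tbl
}
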