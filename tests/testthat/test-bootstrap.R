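test_that("periodic_mean averages by phase from the first valid index", {
  expect_equal(periodic_mean(c(1, 2, 3, 1, 2, 3), 3), c(1, 2, 3))
  expect_equal(periodic_mean(c(1, 2, 3, 5), 3), c(3, 2, 3))
  sim <- weekly_sim(seed = 1, n = 70, amplitude = 1)
  noisefree <- simulate_series(synthetic_spec(
    70, list(component_spec(7, 1))))
  expect_equal(periodic_mean(noisefree$series, 7),
               noisefree$ground_truth[["7"]], tolerance = 1e-12)
  # phases counted from the first valid observation of a masked series
  x <- regular_series(c(NA, 10, 20, 30, 10, 20, 30),
                      valid = c(FALSE, rep(TRUE, 6)))
  expect_equal(periodic_mean(x, 3), c(10, 20, 30))
  expect_error(periodic_mean(c(1, 2), 3), "phase")
})

test_that("gsbb_resample preserves phase and block structure", {
  p <- 7
  v <- rnorm(10 * p + 3)                 # partial last cycle dropped
  set.seed(31)
  for (rep in 1:50) {
    r <- gsbb_resample(v, p)
    expect_length(r, 10 * p)
    src <- attr(r, "source_index")
    expect_identical(src %% p, (seq_along(r) - 1L) %% p)  # phase preserved
    expect_equal(as.numeric(r), v[src + 1L])
  }
  # phase-coded series: every resample reproduces the input exactly
  coded <- rep(0:(13 - 1), times = 6)
  for (rep in 1:20) expect_equal(as.numeric(gsbb_resample(coded, 13)), coded)
  expect_error(gsbb_resample(rnorm(10), 7), "two complete cycles")
})

test_that("with n = 2p both blocks can repeat a single source block", {
  p <- 5
  set.seed(17)
  v <- c(rnorm(p), rnorm(p) + 100)
  seen <- replicate(200, {
    r <- gsbb_resample(v, p)
    paste(unique(attr(r, "source_index") %/% p), collapse = "")
  })
  expect_true("0" %in% seen)   # both blocks drawn from block 0
  r0 <- NULL
  set.seed(18)
  repeat {
    r <- gsbb_resample(v, p)
    if (all(attr(r, "source_index") %/% p == 0)) { r0 <- r; break }
  }
  expect_equal(as.numeric(r0), rep(v[1:p], 2))
})

test_that("bootstrap_band is reproducible and consistent with the naive path", {
  sim <- weekly_sim(seed = 3, n = 364)
  cfg <- bootstrap_config(B = 50, alpha = 0.05, seed = 77)
  b1 <- bootstrap_band(sim$series, 7, cfg)
  b2 <- bootstrap_band(sim$series, 7, cfg)
  expect_identical(b1, b2)
  expect_false(identical(
    b1$lower, bootstrap_band(sim$series, 7,
                             bootstrap_config(50, 0.05, 78))$lower))
  # fast row-means route equals periodic_mean(gsbb_resample(.)) draws
  set.seed(cfg$seed)
  naive <- replicate(cfg$B, periodic_mean(gsbb_resample(sim$series, 7), 7))
  expect_equal(b1$lower,
               apply(naive, 1, stats::quantile, probs = 0.025, names = FALSE),
               tolerance = 1e-12)
  expect_equal(b1$point_estimate, periodic_mean(sim$series, 7))
})

test_that("degenerate resampling collapses the band onto the point estimate", {
  coded <- rep(c(5, -2, 9), times = 10)
  cfg <- bootstrap_config(B = 30, alpha = 0.05, seed = 1)
  band <- bootstrap_band(coded, 3, cfg)
  expect_equal(band$lower, band$point_estimate)
  expect_equal(band$upper, band$point_estimate)
  # B = 1: both bounds equal that single resample's periodic mean
  set.seed(9)
  x <- rnorm(40)
  band1 <- bootstrap_band(x, 5, bootstrap_config(B = 1, alpha = 0.05, seed = 4))
  set.seed(4)
  single <- periodic_mean(gsbb_resample(x, 5), 5)
  expect_equal(band1$lower, single)
  expect_equal(band1$upper, single)
})

test_that("narrower alpha bands nest inside wider ones", {
  sim <- weekly_sim(seed = 6, n = 364)
  b05 <- bootstrap_band(sim$series, 7, bootstrap_config(400, 0.05, 11))
  b10 <- bootstrap_band(sim$series, 7, bootstrap_config(400, 0.10, 11))
  expect_true(all(b10$lower >= b05$lower))
  expect_true(all(b10$upper <= b05$upper))
})

test_that("95% band covers the true periodic mean at roughly nominal rate", {
  # moderate-size check; the full-scale coverage experiment lives in the
  # acceptance suite
  truth <- cos(2 * pi * (0:6) / 7)
  hits <- 0L; total <- 0L
  for (s in 1:60) {
    sim <- weekly_sim(seed = 1000 + s, n = 364)
    band <- bootstrap_band(sim$series, 7, bootstrap_config(300, 0.05, s))
    hits <- hits + sum(band$lower <= truth & truth <= band$upper)
    total <- total + 7L
  }
  expect_gt(hits / total, 0.85)
  expect_lte(hits / total, 1)
})
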