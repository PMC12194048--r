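# Independent oracles and small fixtures shared across tests.

# Polynomial-expansion oracle for the KZ coefficients: expand
# (1 + z + ... + z^(m-1))^k by FFT polynomial multiplication and round
# back to the exact integers, then normalize by m^k.  Independent of the
# shift-and-add route used by kz_coefficients().
poly_kz_oracle <- function(m, k) {
  u <- rep(1, m)
  w <- 1
  for (i in seq_len(k)) {
    w <- round(stats::convolve(w, rev(u), type = "open"))
  }
  w / m^k
}

# Direct-summation oracle for the KZFT at a single time point:
# sum_s a_s x[t+s] exp(-i 2 pi nu s), 1-based t.
kzft_direct <- function(x, m, k, nu, t) {
  w <- as.numeric(kz_coefficients(m, k))
  h <- k * (m - 1) / 2
  s <- -h:h
  sum(w * x[t + s] * exp(-1i * 2 * pi * nu * s))
}

# Short noisy weekly series used by several bootstrap tests.
weekly_sim <- function(seed = 42, n = 364, amplitude = 1) {
  simulate_series(synthetic_spec(
    n = n,
    components = list(component_spec(7, amplitude)),
    noise_sd = 1, ar1 = 0.3, seed = seed))
}

# Rotate a ground-truth phase-mean vector so its phase 0 matches a
# component's band anchor (the first valid observation of the filtered
# series, 0-based global index fv - 1).
align_truth <- function(gt, comp) {
  p <- length(gt)
  fv0 <- (which(comp$valid)[1] - 1L) %% p
  gt[(fv0 + 0:(p - 1L)) %% p + 1L]
}
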