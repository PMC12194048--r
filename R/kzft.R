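#' Kolmogorov-Zurbenko filter coefficients
#'
#' The KZ filter of window `m` (odd) and `k` iterations is the k-fold
#' iterated simple moving average.  Its impulse response is the k-fold
#' self-convolution of the uniform length-`m` window: the coefficients of
#' the polynomial \eqn{(1 + z + \cdots + z^{m-1})^k / m^k}, a symmetric
#' nonnegative vector of length `k(m-1)+1` summing to one.
#'
#' Coefficients are accumulated by exact shift-and-add polynomial
#' multiplication, so they are integer multiples of `1/m^k` with no
#' floating-point convolution error (exact as long as `m^k < 2^53`).
#'
#' @param m Positive odd integer window length.
#' @param k Positive integer number of iterations.
#'
#' @return Numeric vector of length `k*(m-1)+1`, class `"kz_coefficients"`,
#'   with attributes `m` and `k`.  Index `i` corresponds to lag
#'   `s = i - 1 - k(m-1)/2`.
#' @export
#' @examples
#' kz_coefficients(3, 1)  # simple moving average: 1/3, 1/3, 1/3
#' kz_coefficients(3, 2)  # triangular: (1,2,3,2,1)/9
kz_coefficients <- function(m, k) {
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != round(m) ||
      m %% 2 == 0)
    stop("`m` must be a positive odd integer")
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  m <- as.integer(m); k <- as.integer(k)
  w <- 1
  for (iter in seq_len(k)) {
    acc <- numeric(length(w) + m - 1L)
    for (j in seq_len(m)) {
      idx <- j:(j + length(w) - 1L)
      acc[idx] <- acc[idx] + w
    }
    w <- acc
  }
  structure(w / m^k, class = "kz_coefficients", m = m, k = k)
}

#' KZFT filter specification
#'
#' Bundles the three arguments of the KZ Fourier transform filter: window
#' length `m`, iterations `k`, and centre frequency `nu` in cycles per
#' sample.  With `nu = 0` the KZFT reduces to the low-pass KZ filter.
#'
#' When `nu * m` is not an integer the filtered signal suffers a phase
#' shift and loses fidelity; the filter specification records this in the
#' `nu_m_integer` flag rather than refusing, because window lengths in use
#' for short periods (e.g. `m = 741` at `nu = 1/20`) violate it by design.
#'
#' @param m Positive odd integer window length.
#' @param k Positive integer iterations.
#' @param nu Centre frequency in cycles/sample, in `[0, 0.5]`.
#'
#' @return Object of class `"kzft_spec"`.
#' @export
kzft_spec <- function(m, k = 1L, nu = 0) {
  if (length(nu) != 1L || !is.finite(nu) || nu < 0 || nu > 0.5)
    stop("`nu` must lie in [0, 0.5] cycles/sample")
  coef <- kz_coefficients(m, k)   # validates m, k
  num <- nu * m
  structure(list(m = as.integer(m), k = as.integer(k), nu = nu,
                 nu_m_integer = abs(num - round(num)) < 1e-9),
            class = "kzft_spec")
}

#' @export
print.kzft_spec <- function(x, ...) {
  cat(sprintf("<kzft_spec> m = %d, k = %d, nu = %.6g cycles/sample\n",
              x$m, x$k, x$nu))
  if (!x$nu_m_integer)
    cat("  note: nu * m is not an integer; expect phase shift and reduced fidelity\n")
  invisible(x)
}

# Half-width of the invalid edge region of a KZ/KZFT filter.
kz_halfwidth <- function(m, k) as.integer(k * (m - 1L) / 2L)

# Centred convolution of a numeric or complex vector with a symmetric
# weight vector; returns full-length vector with NA (or NA complex) where
# the window does not fit.  stats::filter does the real work.
conv_centered <- function(v, w) {
  if (is.complex(v)) {
    re <- stats::filter(Re(v), w, method = "convolution", sides = 2)
    im <- stats::filter(Im(v), w, method = "convolution", sides = 2)
    return(as.numeric(re) + 1i * as.numeric(im))
  }
  as.numeric(stats::filter(v, w, method = "convolution", sides = 2))
}

#' Apply the KZ low-pass filter
#'
#' Computes \eqn{KZ_{m,k}(t) = \sum_s a_s^{k,m} X(t+s)} by a single
#' convolution with the order-`k(m-1)+1` coefficient vector, which is
#' mathematically identical to `k` iterated moving-average passes.
#' Positions within `k(m-1)/2` of either end of the valid region do not
#' admit the full window and are marked invalid (no shrinking windows, no
#' padding).
#'
#' @param x A [regular_series()], `pc_component`, or numeric vector.
#' @param spec A [kzft_spec()]; its `nu` is ignored here.
#'
#' @return A `regular_series` of the same length with an eroded validity
#'   mask.
#' @export
#' @examples
#' x <- regular_series(seq_len(20))
#' apply_kz(x, kzft_spec(m = 5, k = 1))  # linear trend passes untouched
apply_kz <- function(x, spec) {
  stopifnot(inherits(spec, "kzft_spec"))
  x <- as_regular_series(x)
  v <- valid_values(x)
  h <- kz_halfwidth(spec$m, spec$k)
  if (length(v) < 2L * h + 1L)
    stop(sprintf("series has %d valid points but the filter window needs %d",
                 length(v), 2L * h + 1L))
  w <- kz_coefficients(spec$m, spec$k)
  f <- conv_centered(v, as.numeric(w))
  out <- rep(NA_real_, length(x$values))
  fv <- first_valid_index(x)
  out[fv + seq_along(v) - 1L] <- f
  valid <- !is.na(out)
  regular_series(out, start = x$start, valid = valid)
}

#' Apply the KZFT bandpass filter (complex demodulation)
#'
#' Computes \eqn{KZFT_{m,k,\nu}(t) = \sum_s a_s^{k,m}\, X(t+s)\,
#' e^{-i 2\pi\nu s}} via demodulate-filter-remodulate: the series is
#' multiplied by \eqn{e^{-i2\pi\nu t}}, low-pass filtered with the KZ
#' coefficients, and re-modulated, which equals the direct sum exactly.
#' The result is a complex series whose modulus is half the amplitude of
#' an in-band cosine and whose argument tracks its phase.
#'
#' @param x A [regular_series()] or numeric/complex vector.  Complex input
#'   is accepted so pure complex exponentials can be used to measure the
#'   empirical transfer function.
#' @param spec A [kzft_spec()].
#'
#' @return Object of class `"kzft_demod"`: list with complex `z` (NA off
#'   the valid support), logical `valid`, the `spec`, and the input anchor.
#' @export
apply_kzft <- function(x, spec) {
  stopifnot(inherits(spec, "kzft_spec"))
  if (is.complex(x)) {
    vals <- x
    valid_in <- rep(TRUE, length(x))
    start <- NULL
    fv <- 1L
  } else {
    xs <- as_regular_series(x)
    vals <- xs$values[xs$valid]
    valid_in <- xs$valid
    start <- xs$start
    fv <- first_valid_index(xs)
  }
  h <- kz_halfwidth(spec$m, spec$k)
  if (length(vals) < 2L * h + 1L)
    stop(sprintf("series has %d valid points but the filter window needs %d",
                 length(vals), 2L * h + 1L))
  if (h == 0L) {
    # degenerate window: only s = 0 contributes and e^0 = 1, so the
    # filter is the identity exactly (no demodulation roundoff)
    z_valid <- vals + 0i
  } else {
    # global 0-based time index of each valid observation; phases kept in
    # [0, 2*pi) so trig arguments stay small for long series
    t0 <- (fv - 1L) + (seq_along(vals) - 1L)
    ph <- 2 * pi * ((spec$nu * t0) %% 1)
    demod <- vals * complex(real = cos(ph), imaginary = -sin(ph))
    w <- as.numeric(kz_coefficients(spec$m, spec$k))
    f <- conv_centered(demod, w)
    z_valid <- f * complex(real = cos(ph), imaginary = sin(ph))
  }
  n <- length(valid_in)
  z <- rep(NA_complex_, n)
  z[fv + seq_along(vals) - 1L] <- z_valid
  valid <- !is.na(Re(z))
  structure(list(z = z, valid = valid, spec = spec, start = start),
            class = "kzft_demod")
}

#' Reconstruct the real periodic component from a KZFT output
#'
#' A real in-band cosine of amplitude A appears in the KZFT output as a
#' rotating phasor of modulus A/2 (the one-sided spectrum); taking
#' \eqn{2\,\mathrm{Re}(z)} recovers the real-valued component.  For
#' `nu = 0` the output is already real and no doubling applies.
#'
#' @param zd A `"kzft_demod"` from [apply_kzft()].
#' @param p Optional integer bootstrap period to attach; defaults to
#'   `round(1/nu)`.
#'
#' @return Object of class `"pc_component"`: list with `series` (a
#'   `regular_series` holding the reconstructed component), `nu`, `p`,
#'   and `valid`.
#' @export
reconstruct <- function(zd, p = NULL) {
  stopifnot(inherits(zd, "kzft_demod"))
  nu <- zd$spec$nu
  if (nu == 0) {
    vals <- Re(zd$z)
    if (is.null(p)) stop("`p` must be given explicitly when nu = 0")
  } else {
    vals <- 2 * Re(zd$z)
    if (is.null(p)) p <- as.integer(round(1 / nu))
  }
  p <- as.integer(p)
  if (p < 2L) stop("bootstrap period `p` must be at least 2")
  ser <- regular_series(ifelse(zd$valid, vals, NA_real_),
                        start = zd$start, valid = zd$valid)
  structure(list(series = ser, nu = nu, p = p, valid = zd$valid),
            class = "pc_component")
}

#' @export
print.pc_component <- function(x, ...) {
  cat(sprintf("<pc_component> nu = %.6g cycles/sample, bootstrap period p = %d\n",
              x$nu, x$p))
  cat(sprintf("  %d valid points of %d\n", sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Analytic transfer-function magnitude of the KZFT filter
#'
#' Closed-form gain of the KZFT at a probe frequency:
#' \deqn{\left|\frac{\sin(\pi m \Delta)}{m \sin(\pi \Delta)}\right|^k,
#' \quad \Delta = \nu' - \nu,}
#' the Dirichlet kernel of the uniform window raised to the iteration
#' count.  The gain is 1 at the centre frequency, even in \eqn{\Delta},
#' and exactly 0 whenever \eqn{m\Delta} is a nonzero integer (for
#' \eqn{\Delta} not itself an integer).
#'
#' @param spec A [kzft_spec()].
#' @param probe_nu Frequency (cycles/sample) of the probing sinusoid; may
#'   be a vector.
#'
#' @return Nonnegative gain, vectorized over `probe_nu`.
#' @export
#' @examples
#' s <- kzft_spec(m = 21, k = 1, nu = 1 / 7)
#' kzft_gain(s, 1 / 7)        # 1 at the centre
#' kzft_gain(s, 1 / 7 + 1/21) # first Dirichlet zero
kzft_gain <- function(spec, probe_nu) {
  stopifnot(inherits(spec, "kzft_spec"))
  delta <- probe_nu - spec$nu
  den <- sin(pi * delta)
  num <- sin(pi * spec$m * delta)
  g <- ifelse(abs(den) < 1e-12, 1, abs(num / (spec$m * den)))
  g^spec$k
}
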