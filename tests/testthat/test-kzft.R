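test_that("KZ coefficients match the polynomial-expansion oracle exactly", {
  expect_equal(as.numeric(kz_coefficients(3, 1)), rep(1, 3) / 3)
  expect_equal(as.numeric(kz_coefficients(1, 5)), 1)
  expect_equal(as.numeric(kz_coefficients(3, 2)), c(1, 2, 3, 2, 1) / 9)
  for (m in c(1L, 3L, 5L, 7L, 9L)) {
    for (k in 1:3) {
      w <- kz_coefficients(m, k)
      expect_identical(as.numeric(w), poly_kz_oracle(m, k))
      expect_length(w, k * (m - 1) + 1)
      expect_equal(as.numeric(w), rev(as.numeric(w)))  # symmetric
      expect_true(all(w >= 0))
      expect_equal(sum(w), 1, tolerance = 1e-12)
    }
  }
  expect_error(kz_coefficients(4, 1), "odd")
  expect_error(kz_coefficients(0, 1), "odd")
  expect_error(kz_coefficients(3, 0), "positive")
})

test_that("KZ low-pass preserves constants and linear trends, damps noise", {
  x <- regular_series(rep(2.5, 40))
  f <- apply_kz(x, kzft_spec(7, 2))
  expect_equal(valid_values(f), rep(2.5, 40 - 2 * 6), tolerance = 1e-12)
  # symmetric weights pass a linear trend unchanged on the valid support
  lin <- regular_series(as.numeric(1:50))
  fl <- apply_kz(lin, kzft_spec(5, 1))
  expect_equal(valid_values(fl), as.numeric(3:48), tolerance = 1e-12)
  # white-noise variance shrinks by sum of squared weights = 19/81
  set.seed(11)
  wn <- regular_series(rnorm(60000))
  fw <- apply_kz(wn, kzft_spec(3, 2))
  expect_equal(stats::var(valid_values(fw)), 19 / 81, tolerance = 0.03)
})

test_that("edge contract: exactly k(m-1)/2 invalid points at each end", {
  x <- regular_series(rnorm(100))
  for (mk in list(c(5, 1), c(7, 2), c(3, 3))) {
    f <- apply_kz(x, kzft_spec(mk[1], mk[2]))
    h <- as.integer(mk[2] * (mk[1] - 1) / 2)
    expect_identical(which(!f$valid), c(seq_len(h), 100L - h + seq_len(h)))
  }
  expect_error(apply_kz(regular_series(rnorm(5)), kzft_spec(7, 1)), "window")
})

test_that("KZFT matches direct summation and reduces to KZ at nu = 0", {
  set.seed(3)
  x <- rnorm(200)
  zd <- apply_kzft(regular_series(x), kzft_spec(21, 1, nu = 1 / 7))
  for (t in c(11, 50, 190))
    expect_equal(zd$z[t], kzft_direct(x, 21, 1, 1 / 7, t), tolerance = 1e-12)
  z0 <- apply_kzft(regular_series(x), kzft_spec(21, 1, nu = 0))
  kz <- apply_kz(regular_series(x), kzft_spec(21, 1))
  expect_equal(Re(z0$z[z0$valid]), valid_values(kz), tolerance = 1e-12)
  expect_equal(max(abs(Im(z0$z[z0$valid]))), 0, tolerance = 1e-12)
  expect_error(kzft_spec(21, 1, nu = 0.7), "0, 0.5")
})

test_that("an in-band cosine demodulates to a half-amplitude phasor", {
  nu <- 1 / 7
  t <- 0:1000
  phi <- 0.9
  x <- regular_series(cos(2 * pi * nu * t + phi))
  zd <- apply_kzft(x, kzft_spec(21, 1, nu = nu))   # nu * m = 3, integer
  zv <- zd$z[zd$valid]
  expect_lt(max(abs(Mod(zv) - 0.5)), 1e-6)
  expected <- 0.5 * exp(1i * (2 * pi * nu * t[zd$valid] + phi))
  expect_lt(max(Mod(zv - expected)), 1e-6)
})

test_that("a constant series is annihilated at a Dirichlet-kernel zero", {
  x <- regular_series(rep(5, 1500))
  zd <- apply_kzft(x, kzft_spec(721, 1, nu = 1 / 7))  # nu*m = 103, integer
  expect_lt(max(Mod(zd$z[zd$valid])), 1e-10 * 5)
})

test_that("empirical gain agrees with the closed-form transfer function", {
  t <- 0:3000
  for (k in 1:2) {
    spec <- kzft_spec(101, k, nu = 0.1)
    tol <- if (k == 1) 1e-8 else 1e-6
    for (dnu in c(-0.04, -0.013, 0.0007, 0.0099, 1 / 101, 0.02, 0.07)) {
      probe <- 0.1 + dnu
      x <- complex(argument = 2 * pi * ((probe * t) %% 1))
      zd <- apply_kzft(x, spec)
      emp <- mean(Mod(zd$z[zd$valid]))
      expect_equal(emp, kzft_gain(spec, probe), tolerance = tol)
    }
  }
  # gain facts: unity at centre, even in the offset, k=2 is k=1 squared,
  # exact zero when m * offset is a nonzero integer
  s1 <- kzft_spec(35, 1, nu = 0.2)
  s2 <- kzft_spec(35, 2, nu = 0.2)
  expect_equal(kzft_gain(s1, 0.2), 1)
  expect_equal(kzft_gain(s1, 0.2 + 0.013), kzft_gain(s1, 0.2 - 0.013))
  expect_equal(kzft_gain(s2, 0.23), kzft_gain(s1, 0.23)^2, tolerance = 1e-12)
  expect_equal(kzft_gain(s1, 0.2 + 2 / 35), 0, tolerance = 1e-12)
})

test_that("the KZFT is linear", {
  set.seed(9)
  x <- rnorm(300); y <- rnorm(300)
  spec <- kzft_spec(31, 1, nu = 0.07)
  za <- apply_kzft(regular_series(2 * x + 3 * y), spec)$z
  zx <- apply_kzft(regular_series(x), spec)$z
  zy <- apply_kzft(regular_series(y), spec)$z
  keep <- !is.na(za)
  expect_lt(max(Mod(za[keep] - (2 * zx[keep] + 3 * zy[keep]))), 1e-10)
})

test_that("reconstruction recovers a pure tone and rejects an off-band tone", {
  nu <- 1 / 7
  t <- 0:1459
  x <- regular_series(cos(2 * pi * nu * t + 0.4))
  comp <- reconstruct(apply_kzft(x, kzft_spec(721, 1, nu = nu)))
  expect_identical(comp$p, 7L)
  err <- valid_values(comp) - cos(2 * pi * nu * t[comp$valid] + 0.4)
  expect_lt(max(abs(err)), 0.01)
  # tone at a Dirichlet zero of the m = 721 window centred at 1/7:
  # offset 103/721 puts m * offset at an integer
  nu2 <- 1 / 7 + 103 / 721 / 103   # = 1/7 + 1/721
  x2 <- regular_series(cos(2 * pi * nu2 * t))
  comp2 <- reconstruct(apply_kzft(x2, kzft_spec(721, 1, nu = nu)), p = 7)
  expect_lt(max(abs(valid_values(comp2))), 1e-6)
  # zero in, zero out
  z0 <- apply_kzft(regular_series(rep(0, 100)), kzft_spec(21, 1, nu = 1 / 7))
  expect_equal(valid_values(reconstruct(z0)), rep(0, 100 - 20))
  expect_error(reconstruct(apply_kzft(regular_series(rnorm(50)),
                                      kzft_spec(11, 1, nu = 0))),
               "`p` must be given")
})

test_that("non-integer nu * m is recorded on the filter specification", {
  expect_false(kzft_spec(741, 1, nu = 1 / 20)$nu_m_integer)
  expect_true(kzft_spec(1095, 1, nu = 1 / 365)$nu_m_integer)
  expect_true(kzft_spec(1095, 1, nu = 2 / 365)$nu_m_integer)
  expect_false(kzft_spec(729, 1, nu = 1 / 7)$nu_m_integer)
})
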