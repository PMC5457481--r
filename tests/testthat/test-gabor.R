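test_that("1-D Gabor evaluation follows the closed form", {
  g <- gabor_params(amplitude = 1, x0 = 0, sigma = 4, freq = 0.1, phase = 0)
  grid <- seq(-9, 9)
  prof <- make_gabor_1d(g, grid)
  expect_equal(prof[grid == 0], 1)              # envelope and carrier both 1
  # even symmetry at zero phase
  expect_equal(prof, rev(prof))
  gq <- gabor_params(sigma = 4, freq = 0.1, phase = pi / 2, x0 = 2)
  expect_equal(make_gabor_1d(gq, seq(-9, 9))[grid == 2], 0)
  expect_error(gabor_params(sigma = -1, freq = 0.1), "sigma")
  expect_error(gabor_params(sigma = 1, freq = 0), "freq")
})

test_that("octave-bandwidth relation is exact, invertible, and matches FFT", {
  # printed instantiation value: f = 0.0625 cyc/px, b = 1.5 octaves
  expect_equal(sigma_from_bandwidth(0.0625, 1.5), 6.27, tolerance = 0.01 / 6.27)
  for (b in c(1, 1.5, 2.5, 3.5)) {
    s <- sigma_from_bandwidth(0.08, b)
    expect_equal(bandwidth_octaves(0.08, s), b, tolerance = 1e-10)
  }
  # non-parametric check: FWHM of the synthesized spectrum within 2%
  for (b in c(1, 1.5, 2, 3.5)) {
    s <- sigma_from_bandwidth(0.0625, b)
    fftb <- gabor_bandwidth_fft(gabor_params(sigma = s, freq = 0.0625))
    expect_equal(fftb, b, tolerance = 0.02)
  }
  expect_warning(bandwidth_octaves(0.05, 0.5), "NaN")
})

test_that("two-stage Gabor fitting recovers parameters", {
  grid <- seq_len(19) - 10
  truth <- gabor_params(amplitude = 2, x0 = 1.5, sigma = 4, freq = 0.09,
                        phase = 0.7)
  fit <- fit_gabor_1d(make_gabor_1d(truth, grid), grid)
  expect_gt(fit$r2, 0.999)
  expect_equal(fit$params$amplitude, 2, tolerance = 0.01)
  expect_equal(fit$params$x0, 1.5, tolerance = 0.015)
  expect_equal(fit$params$sigma, 4, tolerance = 0.01)
  expect_equal(fit$params$freq, 0.09, tolerance = 0.01)
  expect_equal(fit$params$phase, 0.7, tolerance = 0.01)

  # simulate-and-recover under noise: frequency stays in the +-10% FFT band
  withr::with_seed(11, {
    for (i in 1:5) {
      tr <- gabor_params(amplitude = 1, x0 = runif(1, -3, 3),
                         sigma = runif(1, 2.5, 5), freq = runif(1, 0.07, 0.15),
                         phase = runif(1, -3, 3))
      y <- make_gabor_1d(tr, grid) + rnorm(19, 0, 0.1)
      f <- fit_gabor_1d(y, grid)
      expect_gt(f$r2, 0.9)
      expect_lt(abs(f$params$freq - tr$freq) / tr$freq, 0.25)
    }
  })
  expect_error(fit_gabor_1d(numeric(19), grid), "degenerate")
  expect_error(fit_gabor_1d(1:5), "length")
})

test_that("binocular Gabor construction implements position/phase encoding", {
  base <- gabor_params(sigma = 3, freq = 0.1, theta = pi / 2)
  rf0 <- make_binocular_gabor(base, 0, 0, c(19, 19))
  expect_identical(rf0$wl, rf0$wr)
  # pure position offset: right field is a translated copy (interior pixels)
  rf4 <- make_binocular_gabor(base, dx0 = 4, dphi = 0, shape = c(25, 25))
  expect_equal(rf4$wr[, 5:25], rf4$wl[, 1:21], tolerance = 1e-12)
  # phase offset of pi inverts polarity
  rfp <- make_binocular_gabor(base, dx0 = 0, dphi = pi, shape = c(19, 19))
  expect_equal(rfp$wr, -rfp$wl, tolerance = 1e-12)
  expect_warning(make_binocular_gabor(gabor_params(sigma = 8, freq = 0.1),
                                      shape = c(19, 19)), "envelope")
})

test_that("encoding classification recovers offsets and wraps phase", {
  enc3 <- classify_encoding(test_rf(dx0 = 3, dphi = 0))
  expect_true(enc3$ok)
  expect_equal(enc3$dx0, 3, tolerance = 0.05)
  expect_equal(enc3$dphi, 0, tolerance = 0.05)

  encp <- classify_encoding(test_rf(dx0 = 0, dphi = pi / 2))
  expect_equal(encp$dphi, pi / 2, tolerance = 0.05)

  # near the wrap point the reported phase stays in [-pi, pi)
  withr::with_seed(4, {
    rf <- test_rf(dx0 = 0, dphi = 0.9 * pi)
    rf$wl <- rf$wl + matrix(rnorm(361, 0, 0.01), 19)
    rf$wr <- rf$wr + matrix(rnorm(361, 0, 0.01), 19)
    enc <- classify_encoding(rf)
    expect_true(enc$dphi >= -pi && enc$dphi <= pi)
    expect_equal(abs(enc$dphi), 0.9 * pi, tolerance = 0.1)
  })

  # wrapping is idempotent with a canonical endpoint
  w <- binodepth:::wrap_phase
  expect_equal(w(w(seq(-10, 10, by = 0.37))), w(seq(-10, 10, by = 0.37)))
  expect_equal(w(pi), w(-pi))
})

test_that("fitted parameters export one row per unit per eye", {
  rfs <- list(test_rf(2, 0), test_rf(0, pi / 3))
  path <- tempfile(fileext = ".csv")
  out <- write_rf_params_csv(rfs, path)
  expect_equal(nrow(out), 4)
  expect_setequal(unique(out$eye), c("left", "right"))
  expect_true(file.exists(path))
})
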