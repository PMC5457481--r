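test_that("simple-unit responses follow the energy-model form", {
  rf <- test_rf(0, 0)
  zero <- stereo_pair(matrix(0, 19, 19), matrix(0, 19, 19))
  for (k in c("relu", "squaring", "rectified-squaring"))
    expect_equal(simple_response(rf, zero, nonlinearity(k)), 0)
  expect_equal(simple_response(rf, zero, nonlinearity("power", 0.5)), 0)

  # rectified-linear output is nonnegative for any stimulus
  withr::with_seed(2, {
    for (i in 1:10) {
      p <- stereo_pair(matrix(runif(361, -1, 1), 19),
                       matrix(runif(361, -1, 1), 19))
      expect_gte(simple_response(rf, p, nonlinearity("relu")), 0)
    }
  })

  # direct inner-product oracle with the fields themselves as stimuli
  sc <- max(abs(c(rf$wl, rf$wr)))
  p <- stereo_pair(rf$wl / sc, rf$wr / sc)
  expect_equal(simple_response(rf, p, nonlinearity("squaring")),
               ((sum(rf$wl^2) + sum(rf$wr^2)) / sc)^2)

  expect_error(simple_response(rf, stereo_pair(matrix(0, 5, 5),
                                               matrix(0, 5, 5))), "shape")
  # map mode slides over all valid positions
  big <- make_rds(rds_config(size = 30, disparity = 0, seed = 1))
  m <- simple_response(rf, big, nonlinearity("relu"), mode = "map")
  expect_equal(dim(m), c(12, 12))
  expect_true(all(m >= 0))
})

test_that("disparity tuning peaks at the preferred disparity and inverts", {
  rf <- test_rf(dx0 = 4, dphi = 0)
  tc <- disparity_tuning(rf, nonlinearity("squaring"), -10:10, trials = 300,
                         seed = 2)
  expect_lte(abs(tc$disparity[which.max(tc$mean)] - 4), 1)
  expect_equal(tc$mean, colMeans(tc$trials))

  # monocular unit: flat tuning
  mono <- binocular_rf(rf$wl, rf$wr * 0)
  tm <- disparity_tuning(mono, nonlinearity("squaring"), -10:10, trials = 200,
                         seed = 3)
  expect_lt(sd(tm$mean) / mean(tm$mean), 0.05)

  # anticorrelation inverts the tuning
  ta <- disparity_tuning(rf, nonlinearity("squaring"), -10:10, trials = 300,
                         correlation = "anticorrelated", seed = 2)
  expect_lt(cor(tc$mean, ta$mean), -0.5)

  # seed invariance within Monte-Carlo error
  tc2 <- disparity_tuning(rf, nonlinearity("squaring"), -10:10, trials = 300,
                          seed = 99)
  expect_gt(cor(tc$mean, tc2$mean), 0.95)
})

test_that("the receptive-field cross-correlogram has the stated structure", {
  rf0 <- test_rf(0, 0)
  cc0 <- rf_cross_correlogram(rf0)
  expect_equal(names(cc0)[which.max(cc0)], "0")   # Cauchy-Schwarz

  rf4 <- test_rf(4, 0, shape = c(25, 25))
  cc4 <- rf_cross_correlogram(rf4, -8:8)
  expect_equal((-8:8)[which.max(cc4)], 4)

  # anticorrelation sign flip
  neg <- binocular_rf(rf4$wl, -rf4$wr)
  expect_equal(rf_cross_correlogram(neg, -8:8), -cc4)
  expect_error(rf_cross_correlogram(rf0, -50:50), "within")
})

test_that("cross-correlogram prediction matches brute-force tuning", {
  # squaring nonlinearity, broadband dot stimuli: affine match r > 0.99
  withr::with_seed(10, {
    base <- gabor_params(sigma = 3.5, freq = 0.11, x0 = -1,
                         phase = 0.8, theta = pi / 2)
    rf <- make_binocular_gabor(base, dx0 = 3, dphi = pi / 3, shape = c(21, 21))
  })
  tc <- disparity_tuning(rf, nonlinearity("squaring"), -10:10, trials = 2000,
                         seed = 5)
  fit <- fit_tuning_prediction(rf, tc)
  expect_gt(fit$r, 0.985)
  expect_gt(fit$energy, 0)
})
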