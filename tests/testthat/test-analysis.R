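test_that("amplitude-ratio bootstrap recovers constructed ratios", {
  grid <- -20:20
  base <- make_gabor_1d(gabor_params(amplitude = 10, x0 = 1, sigma = 6,
                                     freq = 0.07, phase = 0.3), grid) + 2
  withr::with_seed(21, {
    noise <- function() matrix(rnorm(30 * 41, 0, 0.05), 30)
    tc_c <- tuning_curve(grid, matrix(base, 30, 41, byrow = TRUE) + noise())
    tc_half <- tuning_curve(grid,
                            matrix(-0.5 * (base - 2) + 2, 30, 41,
                                   byrow = TRUE) + noise())
    tc_same <- tuning_curve(grid, matrix(base, 30, 41, byrow = TRUE) + noise())
  })
  half <- amplitude_ratio(tc_c, tc_half, n_boot = 100, seed = 1)
  expect_equal(median(half$samples), 0.5, tolerance = 0.05)
  expect_equal(half$point, 0.5, tolerance = 0.05)
  same <- amplitude_ratio(tc_c, tc_same, n_boot = 100, seed = 2)
  expect_equal(median(same$samples), 1, tolerance = 0.05)

  # with no resampling variation a single bootstrap equals the point fit
  flat_c <- tuning_curve(grid, matrix(base, 5, 41, byrow = TRUE))
  flat_a <- tuning_curve(grid, matrix(-0.5 * (base - 2) + 2, 5, 41,
                                      byrow = TRUE))
  one <- amplitude_ratio(flat_c, flat_a, n_boot = 1, seed = 3)
  expect_equal(one$samples, one$point, tolerance = 1e-3)
  expect_error(amplitude_ratio(tc_c, tuning_curve(-5:5,
               matrix(1:11, 2, 11, byrow = TRUE))), "grid")
})

test_that("readout-correlogram correlation is exact for constructed models", {
  m <- init_bnn()
  withr::with_seed(30, {
    m$kernels <- m$kernels + array(rnorm(length(m$kernels), 0, 0.1),
                                   dim(m$kernels))
  })
  lagr <- 1:9
  cc <- vapply(seq_len(28), function(k) {
    u <- bnn_unit_rf(m, k)
    c(mean(rf_cross_correlogram(u, -lagr)), mean(rf_cross_correlogram(u, lagr)))
  }, numeric(2))
  # plant readout weights equal to the correlograms (near row 1, far row 2)
  m$W <- rbind(rep(cc[1, ], each = 36), rep(cc[2, ], each = 36))
  res <- readout_vs_crosscorr(m, lagr)
  expect_equal(res$r, c(1, 1), tolerance = 1e-9)
  flipped <- m; flipped$W <- -m$W
  expect_equal(readout_vs_crosscorr(flipped, lagr)$r, c(-1, -1),
               tolerance = 1e-9)
  expect_error(readout_vs_crosscorr(init_bnn()), "zero")
})

test_that("the step-arrangement decision rule is exact on ground truth", {
  # oracle input separates decision-rule error from model error (noise-free
  # steps make the ground-truth decision unambiguous)
  res <- polarity_task(NULL, n_trials = 12, polarities = "mixed",
                       config = step_edge_config(noise_sd = 0),
                       oracle = TRUE, seed = 5)
  expect_equal(res$prop_correct, 1)

  # and the rule itself: lower (near) half wins
  map <- cbind(matrix(-1, 10, 5), matrix(1, 10, 5))
  expect_equal(binodepth:::step_decision_from_map(map), "left")
  expect_equal(binodepth:::step_decision_from_map(-map), "right")
})
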