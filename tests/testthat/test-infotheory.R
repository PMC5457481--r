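test_that("response distributions are proper conditional histograms", {
  units <- list(test_rf(2, 0, shape = c(19, 21)), test_rf(0, pi / 2,
                                                          shape = c(19, 21)))
  dist <- response_distribution(units, disparities = -6:6, n_stim = 5000,
                                bins = 8, seed = 1)
  expect_equal(colSums(dist$cond), rep(1, 13), tolerance = 1e-9)
  expect_equal(sum(dist$marginal), 1, tolerance = 1e-9)
  # marginal is exactly the prior-weighted mixture of conditionals
  expect_equal(dist$marginal, as.vector(dist$cond %*% dist$prior),
               tolerance = 1e-12)

  # constant-response unit occupies a single bin at every disparity
  const <- binocular_rf(matrix(0, 15, 21), matrix(0, 15, 21), bias = 1)
  dc <- response_distribution(list(const), disparities = -3:3, n_stim = 700,
                              bins = 10, seed = 2)
  expect_true(all(colSums(dc$cond > 0) == 1))
  expect_equal(specific_information(dc), setNames(rep(0, 7), -3:3))
  expect_equal(population_information(dc), 0)

  expect_error(response_distribution(rep(list(const), 6)), "5 units")
})

test_that("specific information matches the hand-computed oracle", {
  # binary response, two equiprobable disparities, p(r=1|d1)=0.9, 0.1
  dist <- structure(list(
    cond = cbind(c(0.1, 0.9), c(0.9, 0.1)),
    marginal = c(0.5, 0.5), prior = c(0.5, 0.5),
    disparities = c(1, 2), bins = 2, n_units = 1,
    bin_edges = list(c(0, 0.5, 1)), n_stim = NA
  ), class = "response_distribution")
  oracle <- 0.9 * log2(0.9 / 0.5) + 0.1 * log2(0.1 / 0.5)
  expect_equal(specific_information(dist, 1), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.531, tolerance = 1e-3)
  expect_error(specific_information(dist, 7), "grid")

  # specific information is a KL divergence: nonnegative everywhere
  units <- list(test_rf(3, 0, shape = c(19, 21)))
  d <- response_distribution(units, disparities = -8:8, n_stim = 6000,
                             seed = 3)
  expect_true(all(specific_information(d) >= 0))
  # mutual information equals the prior-weighted mean of specific information
  expect_equal(population_information(d),
               sum(d$prior * specific_information(d)), tolerance = 1e-12)
})

test_that("a noiseless distinct-response channel attains log2(M) bits", {
  # deterministic responses: one unit whose rate identifies the disparity
  M <- 8
  dist <- structure(list(
    cond = diag(M), marginal = rep(1 / M, M), prior = rep(1 / M, M),
    disparities = seq_len(M), bins = M, n_units = 1,
    bin_edges = list(seq(0, 1, length.out = M + 1)), n_stim = NA
  ), class = "response_distribution")
  expect_equal(population_information(dist), log2(M), tolerance = 1e-12)
})

test_that("coarsening response bins never increases mutual information", {
  units <- list(test_rf(2, pi / 4, shape = c(19, 21)),
                test_rf(-3, 0, shape = c(19, 21)))
  r <- binodepth:::unit_responses(units, nonlinearity("rectified-squaring"),
                                  -6:6, 6000, seed = 4)
  fine <- binodepth:::quantize_responses(r$responses, r$disparity_index,
                                         -6:6, bins = 10)
  coarse <- binodepth:::quantize_responses(r$responses, r$disparity_index,
                                           -6:6, bins = 5)
  expect_gte(population_information(fine) + 1e-12,
             population_information(coarse))
})

test_that("encoding comparison returns the documented schema deterministically", {
  tab1 <- compare_encodings(N = 3, n_pop = 6, disparities = seq(-8, 8, 2),
                            n_stim = 1800, shape = c(13, 21), seed = 5)
  tab2 <- compare_encodings(N = 3, n_pop = 6, disparities = seq(-8, 8, 2),
                            n_stim = 1800, shape = c(13, 21), seed = 5)
  expect_identical(tab1, tab2)
  expect_setequal(tab1$encoding, c("position", "phase", "hybrid"))
  expect_true(all(c("random_mean", "random_sd", "uniform") %in% names(tab1)))
  expect_true(all(tab1$random_mean >= 0))
})
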