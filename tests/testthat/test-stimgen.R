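test_that("random-dot stereograms honor correlation, polarity and density", {
  p0 <- make_rds(rds_config(size = 60, disparity = 0, seed = 1))
  expect_identical(p0$left, p0$right)
  pa <- make_rds(rds_config(size = 60, disparity = 0,
                            correlation = "anticorrelated", seed = 1))
  dots <- pa$left != 0
  expect_true(all(pa$left[dots] == -pa$right[dots]))
  expect_true(all(pa$left[!dots] == pa$right[!dots]))

  # dot coverage matches the nominal density within binomial error
  fracs <- vapply(1:100, function(s)
    mean(make_rds(rds_config(size = 100, density = 0.5, seed = s))$left != 0),
    numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 3 * sqrt(0.25 / (100 * 1e4)))

  # deterministic under seed, intensity invariant holds
  p1 <- make_rds(rds_config(size = 40, disparity = 3, seed = 9))
  p2 <- make_rds(rds_config(size = 40, disparity = 3, seed = 9))
  expect_identical(p1$left, p2$left)
  expect_true(max(abs(p1$left), abs(p1$right)) <= 1)
  expect_error(rds_config(density = 1.5), "density")
})

test_that("correlated RDS cross-correlation peaks at the imposed disparity", {
  for (d in c(-8, -3, 0, 5, 8)) {
    acc <- numeric(17)
    for (s in 1:20) {
      p <- make_rds(rds_config(size = c(30, 60), disparity = d, seed = 100 + s))
      for (k in -8:8) {
        cols <- (1 + 8):(60 - 8)
        acc[k + 9] <- acc[k + 9] + sum(p$left[, cols] * p$right[, cols + k])
      }
    }
    expect_equal((-8:8)[which.max(acc)], d)
    # anticorrelation flips the peak sign
    pa <- make_rds(rds_config(size = c(30, 60), disparity = d,
                              correlation = "anticorrelated", seed = 100))
    cols <- (1 + 8):(60 - 8)
    expect_lt(sum(pa$left[, cols] * pa$right[, cols + d]), 0)
  }
})

test_that("step-edge stereograms impose the configured step and noise", {
  p <- make_step_edge(step_edge_config(noise_sd = 0, seed = 2))
  dots <- p$meta$dots
  cx <- dots$col + 3.5
  near_half <- cx <= 120          # near_side defaults to left
  expect_equal(mean(dots$disparity[!near_half]) - mean(dots$disparity[near_half]), 2)
  expect_true(all(dots$disparity[near_half] == -1))

  # mixed polarity: both contrasts present in (near-)equal numbers
  expect_lte(abs(sum(dots$value == 1) - sum(dots$value == -1)), 1)

  # empirical disparity noise across seeds ~ 8 px (integer-rounded)
  ds <- unlist(lapply(1:40, function(s)
    make_step_edge(step_edge_config(seed = s))$meta$dots$disparity))
  expect_equal(sd(ds), sqrt(64 + 1 + 1 / 12), tolerance = 0.05)

  # dots do not occlude one another in the base layout
  occ <- matrix(0L, 240, 240)
  for (i in seq_len(nrow(dots))) {
    rr <- dots$row[i]:(dots$row[i] + 7); cc <- dots$col[i]:(dots$col[i] + 7)
    occ[rr, cc] <- occ[rr, cc] + 1L
  }
  expect_true(all(occ <= 1L))
})

test_that("luminance controls behave as specified", {
  p <- make_step_edge(step_edge_config(polarity = "bright", seed = 3))
  dc <- polarity_controls(p, "dc-removed")
  expect_lt(abs(mean(dc$left)), 1e-12)
  expect_lt(abs(mean(dc$right)), 1e-12)
  rm_ <- polarity_controls(p, "range-matched")
  expect_equal(range(rm_$left), c(-1, 1))
  # dc removal then range matching equates ranges across polarity conditions
  pm <- make_step_edge(step_edge_config(polarity = "mixed", seed = 3))
  ref <- diff(range(polarity_controls(pm, "dc-removed")$left))
  rb <- polarity_controls(p, "range-matched-after-dc", reference_range = ref)
  expect_equal(diff(range(rb$left)), ref, tolerance = 1e-12)
  expect_lt(abs(mean(rb$left)), 1e-12)
})

test_that("depth rendering shifts pixels and fills disocclusions", {
  withr::with_seed(5, tex <- matrix(runif(80 * 80), 80))
  flat <- render_stereo_from_depth(tex, matrix(0, 80, 80))
  expect_identical(flat$left, flat$right)

  # constant maximum depth: uniform 10-px shift, cross-correlation peak at 10
  far <- render_stereo_from_depth(tex, matrix(1, 80, 80), max_shift = 10)
  xc <- vapply(0:12, function(k) {
    cols <- 13:(80 - 13)
    cor(as.vector(far$left[, cols]), as.vector(far$right[, cols + k]))
  }, numeric(1))
  expect_equal((0:12)[which.max(xc)], 10)

  # fronto-parallel square: local cross-correlation peak at its imposed shift
  depth <- matrix(1, 80, 80); depth[30:60, 30:60] <- 0.5
  sq <- render_stereo_from_depth(tex, depth, max_shift = 8)
  expect_equal(sq$disparity[45, 45], 4)
  xcl <- vapply(0:8, function(k)
    cor(as.vector(sq$left[35:55, 35:50]), as.vector(sq$right[35:55, 35:50 + k])),
    numeric(1))
  expect_equal((0:8)[which.max(xcl)], 4)
  expect_true(any(sq$mask))
  expect_error(render_stereo_from_depth(tex, matrix(NA_real_, 80, 80)), "finite")
})

test_that("synthetic scenes are seeded, power-law, and piecewise-depth", {
  s1 <- synth_scene(scene_spec(size = 128, seed = 21))
  s2 <- synth_scene(scene_spec(size = 128, seed = 21))
  expect_identical(s1$texture, s2$texture)
  expect_identical(s1$depth, s2$depth)

  # radially averaged amplitude spectrum slope ~ -1
  tex <- synth_scene(scene_spec(size = 256, seed = 3))$texture
  a <- Mod(fft(tex - mean(tex)))
  fr <- c(0:(128), -(127:1)) / 256
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  sel <- rad > 0.02 & rad < 0.3
  fitl <- coef(stats::lm(log(a[sel]) ~ log(rad[sel])))
  expect_equal(unname(fitl[2]), -1, tolerance = 0.2)

  # two-surface scene: bimodal depth histogram at the drawn depths
  sc <- synth_scene(scene_spec(size = 128, n_surfaces = 2, seed = 8))
  expect_equal(length(unique(as.vector(sc$depth))), 2)
  expect_true(min(table(sc$depth)) > 200)
})

test_that("patch extraction filters, scales, labels and splits", {
  scenes <- lapply(c(31, 32, 33), function(s)
    synth_scene(scene_spec(size = 160, seed = s)))
  pairs <- lapply(scenes, function(sc)
    render_stereo_from_depth(sc$texture, sc$depth, 10))
  pair <- pairs[[1]]

  # a constant-intensity region is excluded by the variance rule
  flat_tex <- matrix(0.5, 160, 160)
  flat_pair <- render_stereo_from_depth(flat_tex, scenes[[1]]$depth, 10)
  expect_error(extract_patches(list(flat_pair), stride = 30), "too few")

  sets <- extract_patches(pairs, stride = 10, seed = 1)
  n <- sum(vapply(sets, function(s) dim(s$left)[3], 1L))
  expect_equal(dim(sets$train$left)[3], floor(0.7 * n))
  expect_equal(dim(sets$val$left)[3], floor(0.15 * n))
  expect_true(max(abs(sets$train$left)) <= 1)
  expect_setequal(levels(sets$train$label), c("near", "far"))
  # near labels have negative mean disparity, far positive
  expect_true(all(sets$train$disparity[sets$train$label == "near"] < 0))
  expect_true(all(sets$train$disparity[sets$train$label == "far"] > 0))

  # over-interpolated patches are excluded: force a pair whose mask is dense
  dense_mask <- pair
  dense_mask$mask <- matrix(TRUE, 160, 160)
  expect_error(extract_patches(list(dense_mask), stride = 30), "too few")
})

test_that("wallpaper and da Vinci displays have the stated structure", {
  wp <- make_wallpaper(period = 8, size = 120, bg_luminance = -0.4)
  expect_identical(wp$left, wp$right)
  rr <- wp$meta$region_rows[1]:wp$meta$region_rows[2]
  cc <- wp$meta$region_cols[1]:(wp$meta$region_cols[2] - 8)
  # shifting by one period reproduces the pattern (matching ambiguity)
  expect_identical(wp$left[rr, cc], wp$left[rr, cc + 8])
  wp2 <- make_wallpaper(period = 8, size = 120, bg_luminance = 0.4)
  diffpix <- wp$left != wp2$left
  expect_true(all(wp$left[!diffpix] == wp2$left[!diffpix]))
  expect_true(all(wp$left[diffpix] == -0.4 & wp2$left[diffpix] == 0.4))

  dv <- make_davinci(size = 120)
  tr <- dv$meta$target_rows[1]:dv$meta$target_rows[2]
  tc <- dv$meta$target_cols[1]:dv$meta$target_cols[2]
  expect_identical(dv$left[tr, tc], dv$right[tr, tc])   # zero disparity target
  lf <- dv$meta$flank_cols$left_eye[1]:dv$meta$flank_cols$left_eye[2]
  rf <- dv$meta$flank_cols$right_eye[1]:dv$meta$flank_cols$right_eye[2]
  expect_true(all(dv$left[tr, lf] == -1) && all(dv$right[tr, lf] == 0))
  expect_true(all(dv$right[tr, rf] == -1) && all(dv$left[tr, rf] == 0))
  expect_true(all(dv$mask[tr, c(lf, rf)]))
  expect_error(make_davinci(flank_width = 0), "flank_width")
})
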