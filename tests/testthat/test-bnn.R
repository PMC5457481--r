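test_that("architecture counts and shape chain match the published design", {
  m <- init_bnn()
  pc <- bnn_param_count(m)
  expect_equal(pc$conv, 20244)
  expect_equal(pc$conv_units, 4032)
  expect_equal(pc$input_connections, 2911104)
  expect_equal(pc$readout_connections, 1008)
  expect_equal(pc$readout, 1010)
  expect_equal(pc$total, 21254)

  # 30x30x2 -> 28x12x12 -> 28x6x6 -> 2
  x <- array(runif(30 * 30 * 3, -1, 1), c(30, 30, 3))
  fw <- bnn_forward(m, x, x, keep = c("conv", "pooled"))
  expect_equal(dim(fw$conv), c(3 * 144, 28))
  expect_equal(dim(fw$pooled), c(28 * 36, 3))
  expect_equal(ncol(fw$probs), 2)

  # Gabor initialization: no interocular differences, zero readout
  expect_identical(m$kernels[, , 1, ], m$kernels[, , 2, ])
  expect_true(all(m$W == 0) && all(m$b == 0) && all(m$conv_bias == 0))
  expect_equal(fw$probs, matrix(0.5, 3, 2))
  expect_equal(rowSums(fw$probs), rep(1, 3), tolerance = 1e-9)
  expect_error(bnn_forward(m, x[1:20, , , drop = FALSE],
                           x[1:20, , , drop = FALSE]), "30 x 30")
})

test_that("analytic gradients match central finite differences", {
  tiny <- init_bnn(n_outputs = 2, n_kernels = 3, kernel_size = 5,
                   input_size = 8)
  withr::with_seed(3, {
    tiny$kernels <- tiny$kernels +
      array(rnorm(length(tiny$kernels), 0, 0.05), dim(tiny$kernels))
    tiny$conv_bias <- rnorm(3, 0, 0.1)
    tiny$W <- matrix(rnorm(length(tiny$W), 0, 0.3), nrow(tiny$W))
    tiny$b <- rnorm(2, 0, 0.1)
    L <- array(rnorm(8 * 8 * 6, 0, 0.5), c(8, 8, 6))
    R <- array(rnorm(8 * 8 * 6, 0, 0.5), c(8, 8, 6))
  })
  lab <- factor(rep(c("near", "far"), 3), levels = c("near", "far"))
  g <- binodepth:::bnn_gradients(tiny, L, R, lab)
  loss_at <- function(mm) binodepth:::bnn_gradients(mm, L, R, lab)$loss
  eps <- 1e-6
  withr::with_seed(8, {
    for (field in c("kernels", "conv_bias", "W", "b")) {
      gg <- g$grads[[field]]
      idx <- sample(length(gg), min(20, length(gg)))
      fd <- vapply(idx, function(i) {
        m1 <- tiny; m2 <- tiny
        m1[[field]][i] <- m1[[field]][i] + eps
        m2[[field]][i] <- m2[[field]][i] - eps
        (loss_at(m1) - loss_at(m2)) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(fd - gg[idx]) / pmax(abs(fd) + abs(gg[idx]), 1e-8)),
                1e-5)
    }
  })
})

test_that("training reduces the loss and solves a separable toy task", {
  tr <- make_rds_test_set(400, c(-4, 4), seed = 10)
  va <- make_rds_test_set(100, c(-4, 4), seed = 11)
  res <- bnn_train(init_bnn(), tr, va,
                   train_config(max_epochs = 10, patience = 1e6, seed = 5))
  h <- res$history
  expect_equal(nrow(h), 10)
  # early loss trend is downward under the small constant learning rate
  expect_lt(median(diff(h$train_loss)), 0)
  expect_true(all(h$patience >= 1e6))
  expect_error(bnn_train(init_bnn(), tr, va,
                         train_config(batch_size = 99)), "divisible")
})

test_that("bootstrap evaluation reports accuracy with percentile intervals", {
  set <- make_rds_test_set(200, c(-4, 4), seed = 1)
  m <- init_bnn()
  # untrained model guesses; accuracy ~ 50% and CI spans it
  ev <- bnn_evaluate(m, set, n_boot = 200, seed = 2)
  expect_lt(abs(ev$accuracy - 50), 3 * 100 * sqrt(0.25 / 200))
  expect_true(ev$ci[1] <= ev$accuracy && ev$accuracy <= ev$ci[2])
  # all-correct predictions give a degenerate CI at 100 (the untrained
  # model's tie-break always picks the first output)
  allc <- structure(list(left = set$left, right = set$right,
                         label = factor(rep("near", 200),
                                        levels = c("near", "far"))),
                    class = "patch_set")
  ev3 <- bnn_evaluate(m, allc, n_boot = 100, seed = 3)
  expect_equal(ev3$accuracy, 100)
  expect_equal(unname(ev3$ci), c(100, 100))
})

test_that("lesioning removes kernels and their readout exactly", {
  m <- init_bnn()
  withr::with_seed(6, {
    m$W <- matrix(rnorm(length(m$W), 0, 0.1), nrow(m$W))
    m$kernels <- m$kernels + array(rnorm(length(m$kernels), 0, 0.02),
                                   dim(m$kernels))
  })
  x <- array(runif(30 * 30 * 4, -1, 1), c(30, 30, 4))
  expect_identical(bnn_forward(lesion_bnn(m, integer(0)), x, x)$logits,
                   bnn_forward(m, x, x)$logits)
  les <- lesion_bnn(m, 1:7)
  expect_equal(les$n_kernels, 21)
  pc <- bnn_param_count(m); pl <- bnn_param_count(les)
  expect_equal(pc$conv - pl$conv, 7 * (19 * 19 * 2 + 1))
  expect_equal(ncol(m$W) - ncol(les$W), 7 * 36)
  expect_error(lesion_bnn(m, 1:28), "all units")
  expect_error(lesion_bnn(m, 99), "invalid")
})

test_that("drive decomposition reconstructs the logits", {
  m <- init_bnn()
  withr::with_seed(7, m$W <- matrix(rnorm(length(m$W), 0, 0.05), nrow(m$W)))
  m$b <- c(0.2, -0.1)
  x <- array(runif(30 * 30 * 5, -1, 1), c(30, 30, 5))
  dd <- drive_decomposition(m, x, x)
  expect_true(all(dd$excitatory >= 0) && all(dd$suppressive <= 0))
  recon <- dd$excitatory + dd$suppressive +
    matrix(m$b, 5, 2, byrow = TRUE)
  expect_equal(recon, dd$logits, tolerance = 1e-9)
})

test_that("optimal-stimulus ascent increases the objective", {
  m <- init_bnn(n_kernels = 8)
  withr::with_seed(12, {
    m$kernels <- m$kernels + array(rnorm(length(m$kernels), 0, 0.05),
                                   dim(m$kernels))
    m$W <- matrix(rnorm(length(m$W), 0, 0.05), nrow(m$W))
  })
  os <- optimal_stimulus(m, unit = 2, iters = 30, step = 0.5, seed = 3)
  expect_gt(os$objective[30], os$objective[1])
  expect_gt(os$iterate_cor[30], 0.99)
  expect_equal(length(os$snapshots), 3)
  expect_true(max(abs(c(os$pair$left, os$pair$right))) <= 1)
})

test_that("model checkpoints round-trip through serialization", {
  m <- init_bnn(n_kernels = 4)
  path <- tempfile(fileext = ".rds")
  save_bnn(m, path)
  m2 <- load_bnn(path)
  expect_identical(m$kernels, m2$kernels)
  x <- array(runif(30 * 30, -1, 1), c(30, 30, 1))
  expect_identical(bnn_forward(m, x, x)$logits, bnn_forward(m2, x, x)$logits)
})
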