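# Shared fixtures. The trained network is built once per test session and
# reused by every test that needs a trained model; sizes are the reduced
# study conditions described in the methods vignette.

fixture_env <- new.env(parent = emptyenv())

# a small binocular Gabor pair used across unit tests
test_rf <- function(dx0 = 4, dphi = 0, sigma = 3, f = 0.1, shape = c(19, 19)) {
  make_binocular_gabor(gabor_params(sigma = sigma, freq = f,
                                    x0 = -dx0 / 2, phase = wrap_test(-dphi / 2),
                                    theta = pi / 2),
                       dx0 = dx0, dphi = dphi, shape = shape)
}

wrap_test <- function(phi) ((phi + pi) %% (2 * pi)) - pi

# naturalistic patch corpus at test scale
test_corpus <- function() {
  if (is.null(fixture_env$corpus)) {
    fixture_env$corpus <- make_patch_corpus(
      n_scenes = 40, spec = scene_spec(size = 160, n_surfaces = 3),
      max_shifts = c(3, 4), seed = 42, stride = 10,
      min_abs_disp = 2, max_abs_disp = 4)
  }
  fixture_env$corpus
}

# the trained 2-way network (single training run per session)
trained_bnn <- function() {
  if (is.null(fixture_env$bnn)) {
    corpus <- test_corpus()
    n_batches <- min(table(corpus$train$label)) %/% 50
    cfg <- train_config(max_epochs = ceiling(8000 / n_batches),
                        patience = 6000, precision = "single", seed = 7)
    res <- bnn_train(init_bnn(), corpus$train, corpus$val, cfg)
    fixture_env$bnn <- res$model
    fixture_env$history <- res$history
  }
  fixture_env$bnn
}

# signed disparities represented in the training corpus (used to probe the
# trained network at the disparities it was optimized for)
trained_disparities <- function() {
  sort(unique(round(test_corpus()$train$disparity)))
}
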