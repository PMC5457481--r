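#' Initialize the binocular neural network
#'
#' The architecture is fixed: `n_kernels` binocular convolutional kernels
#' (`kernel_size` x `kernel_size` x 2) with a bias each, linear
#' rectification, 2x2 non-overlapping max pooling, and a softmax readout to
#' `n_outputs` decision units. Kernels are initialized as vertically
#' oriented Gabors identical in the two eyes (no disparity selectivity at
#' initialization): f = 0.1 cyc/px, sigma = 3 px, theta = pi/2, phases
#' equally spaced over `[0, pi]`. Convolution biases, readout weights and
#' readout biases start at zero, so an untrained network outputs uniform
#' class probabilities.
#'
#' @param n_outputs Number of output (complex) units (>= 2).
#' @param n_kernels Number of binocular kernels.
#' @param kernel_size Kernel side, pixels.
#' @param input_size Input patch side, pixels.
#' @param seed Unused by the deterministic initialization; recorded in
#'   metadata for provenance.
#' @return An object of class `bnn_model`.
#' @export
init_bnn <- function(n_outputs = 2, n_kernels = 28, kernel_size = 19,
                     input_size = 30, seed = NULL) {
  if (n_outputs < 2) stop("n_outputs must be >= 2")
  phases <- seq(0, pi, length.out = n_kernels)
  kernels <- array(0, c(kernel_size, kernel_size, 2, n_kernels))
  for (k in seq_len(n_kernels)) {
    g <- make_gabor_2d(gabor_params(sigma = 3, freq = 0.1, phase = phases[k],
                                    theta = pi / 2),
                       kernel_size, kernel_size)
    kernels[, , 1, k] <- g
    kernels[, , 2, k] <- g
  }
  conv_out <- input_size - kernel_size + 1
  pooled <- conv_out %/% 2
  model <- structure(list(
    kernels = kernels, conv_bias = numeric(n_kernels), pool = 2L,
    W = matrix(0, n_outputs, n_kernels * pooled^2), b = numeric(n_outputs),
    n_outputs = n_outputs, n_kernels = n_kernels,
    kernel_size = kernel_size, input_size = input_size,
    classes = if (n_outputs == 2) c("near", "far") else
      paste0("class", seq_len(n_outputs)),
    meta = list(seed = seed, trained = FALSE)
  ), class = "bnn_model")
  model
}

#' @export
print.bnn_model <- function(x, ...) {
  pc <- bnn_param_count(x)
  cat(sprintf(paste0("Binocular neural network: %d kernels (%dx%dx2), ",
                     "%d outputs, %s; %d parameters\n"),
              x$n_kernels, x$kernel_size, x$kernel_size, x$n_outputs,
              if (isTRUE(x$meta$trained)) "trained" else "untrained",
              pc$total))
  invisible(x)
}

#' Parameter and connection accounting for the network
#'
#' Mirrors the published accounting: the convolutional layer has
#' `n_kernels * kernel_size^2 * 2` weights plus one bias per kernel; the
#' convolutional layer forms `units * kernel_size^2 * 2` connections to the
#' input; the readout layer has one connection per pooled unit
#' (`n_kernels * pooled^2`) and is counted as those connections plus one
#' bias per output unit.
#'
#' @param model A [bnn_model()].
#' @return List with `conv`, `conv_units`, `input_connections`,
#'   `readout_connections`, `readout`, `total`.
#' @export
bnn_param_count <- function(model) {
  ks2 <- model$kernel_size^2 * 2
  conv <- model$n_kernels * ks2 + model$n_kernels
  conv_out <- model$input_size - model$kernel_size + 1
  conv_units <- model$n_kernels * conv_out^2
  pooled_units <- model$n_kernels * (conv_out %/% 2)^2
  list(conv = conv,
       conv_units = conv_units,
       input_connections = conv_units * ks2,
       readout_connections = pooled_units,
       readout = pooled_units + model$n_outputs,
       total = conv + pooled_units + model$n_outputs)
}

# internal: kernels as a (kh*kw*2 x K) matrix matching stereo_im2col columns
kernel_matrix <- function(model) {
  matrix(model$kernels, ncol = model$n_kernels)
}

# internal: 2x2 non-overlapping max pool with first-occurrence (column-major
# window order) tie-breaking; compiled. `conv` is an (n*P x K) activity
# matrix, P = oh*ow column-major positions. Returns pooled activities in
# readout layout (within-kernel positions fastest, kernels next, one column
# per patch) plus the argmax rows for backprop.
pool_forward <- function(conv, oh, ow, n, K) {
  pool_max_forward(conv, oh, ow, n, K)
}

# internal: route pooled gradients back through the pooling switches.
pool_backward <- function(dpooled, idx, oh, ow, n, K) {
  pool_max_backward(dpooled, idx, oh, ow, n, K)
}

# internal: softmax over rows of a (n x N) logit matrix
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass of the binocular network
#'
#' Valid convolution (stride 1) with the binocular kernels, linear
#' rectification, 2x2 max pooling, affine readout and softmax. The predicted
#' class is the output unit with the highest activity.
#'
#' @param model A [bnn_model()].
#' @param left,right Input patches: matrices (single patch) or
#'   `(h, w, n)` arrays.
#' @param keep Character vector of intermediate results to return in
#'   addition to probabilities, logits and predictions: any of `"pooled"`,
#'   `"conv"`, `"pool_idx"`.
#' @return List with `probs` (n x N), `logits` (n x N), `pred` (integer
#'   class index), and any requested intermediates.
#' @export
bnn_forward <- function(model, left, right, keep = character()) {
  stopifnot(inherits(model, "bnn_model"))
  if (is.matrix(left)) left <- array(left, c(dim(left), 1))
  if (is.matrix(right)) right <- array(right, c(dim(right), 1))
  d <- dim(left)
  if (!identical(dim(right), d)) stop("left/right batch shapes must match")
  if (d[1] != model$input_size || d[2] != model$input_size)
    stop(sprintf("patches must be %d x %d", model$input_size, model$input_size))
  n <- d[3]; K <- model$n_kernels
  kh <- model$kernel_size
  oh <- d[1] - kh + 1; ow <- d[2] - kh + 1
  conv <- pmax(conv_forward(left, right, kernel_matrix(model),
                            model$conv_bias), 0)
  pf <- pool_forward(conv, oh, ow, n, K)
  logits <- t(model$W %*% pf$pooled + model$b)     # n x N
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits,
              pred = max.col(logits, ties.method = "first"))
  if ("pooled" %in% keep) out$pooled <- pf$pooled
  if ("conv" %in% keep) out$conv <- conv
  if ("pool_idx" %in% keep) out$pool_idx <- pf$idx
  out
}

#' Remove simple units from the network
#'
#' Deletes the named kernels together with their biases and all their
#' readout weights; remaining parameters are untouched.
#'
#' @param model A [bnn_model()].
#' @param units Integer indices of the kernels to remove (may be empty).
#' @return The lesioned [bnn_model()].
#' @export
lesion_bnn <- function(model, units) {
  stopifnot(inherits(model, "bnn_model"))
  units <- unique(as.integer(units))
  if (length(units) == 0) return(model)
  if (any(units < 1 | units > model$n_kernels)) stop("invalid unit indices")
  if (length(units) >= model$n_kernels) stop("cannot remove all units")
  keep <- setdiff(seq_len(model$n_kernels), units)
  pooled_per <- ncol(model$W) / model$n_kernels
  keep_cols <- as.vector(outer(seq_len(pooled_per), (keep - 1) * pooled_per, `+`))
  model$kernels <- model$kernels[, , , keep, drop = FALSE]
  model$conv_bias <- model$conv_bias[keep]
  model$W <- model$W[, keep_cols, drop = FALSE]
  model$n_kernels <- length(keep)
  model$meta$lesioned <- units
  model
}

#' Save / load a network checkpoint
#'
#' Checkpoints are written with R's native serialization together with the
#' architecture metadata already stored on the model.
#'
#' @param model A [bnn_model()].
#' @param path File path.
#' @return `save_bnn` the path invisibly; `load_bnn` the model.
#' @export
save_bnn <- function(model, path) {
  stopifnot(inherits(model, "bnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_bnn
#' @export
load_bnn <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "bnn_model"))
  model
}

#' Extract a simple unit's receptive field from the network
#'
#' @param model A [bnn_model()].
#' @param k Kernel index.
#' @return A [binocular_rf()] (left = eye 1, right = eye 2).
#' @export
bnn_unit_rf <- function(model, k) {
  stopifnot(k >= 1, k <= model$n_kernels)
  binocular_rf(model$kernels[, , 1, k], model$kernels[, , 2, k],
               bias = model$conv_bias[k])
}
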