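# internal: gradient of a single output unit's logit with respect to the
# input images (used by the optimal-stimulus search)
bnn_input_gradient <- function(model, left, right, unit) {
  fw <- bnn_forward(model, left, right,
                    keep = c("pooled", "conv", "pool_idx"))
  n <- dim(left)[3]; K <- model$n_kernels
  oh <- model$input_size - model$kernel_size + 1
  dlogits <- matrix(0, n, model$n_outputs)
  dlogits[, unit] <- 1
  dpooled <- crossprod(model$W, t(dlogits))
  dconv <- pool_backward(dpooled, fw$pool_idx, oh, oh, n, K)
  dconv[fw$conv == 0] <- 0
  g <- conv_backward_input(dconv, kernel_matrix(model),
                           model$input_size, model$input_size, n,
                           model$kernel_size, model$kernel_size)
  list(gradient = g, logit = fw$logits[, unit])
}

#' Synthesize the optimal stimulus for an output unit
#'
#' Gradient ascent on the input images: starting from uniform noise, the
#' stereo pair is iteratively adjusted to maximize the chosen output unit's
#' pre-softmax activity (equivalently, to minimize its negated input).
#' The iteration count is capped; convergence is monitored as the
#' correlation between consecutive iterates, which saturates at 1.
#'
#' @param model A trained [bnn_model()].
#' @param unit Output unit index.
#' @param iters Iteration cap (default 100).
#' @param step Gradient step size (default 1).
#' @param noise_sd SD of the Gaussian noise initialization.
#' @param seed Optional RNG seed for the initialization.
#' @return List with `pair` (final [stereo_pair()], intensities clipped for
#'   display only in the returned object's metadata), `objective` (per-iter
#'   logit), `iterate_cor` (correlation between consecutive iterates), and
#'   `snapshots` (first/middle/final pairs).
#' @export
optimal_stimulus <- function(model, unit = 1, iters = 100, step = 1,
                             noise_sd = 0.1, seed = NULL) {
  stopifnot(inherits(model, "bnn_model"), unit >= 1,
            unit <= model$n_outputs)
  s <- model$input_size
  with_seed_if(seed, {
    L <- array(rnorm(s * s, 0, noise_sd), c(s, s, 1))
    R <- array(rnorm(s * s, 0, noise_sd), c(s, s, 1))
    objective <- numeric(iters)
    iterate_cor <- rep(NA_real_, iters)
    snapshots <- list()
    prev <- c(L, R)
    for (it in seq_len(iters)) {
      g <- bnn_input_gradient(model, L, R, unit)
      L <- L + step * g$gradient$left
      R <- R + step * g$gradient$right
      objective[it] <- g$logit
      cur <- c(L, R)
      if (it > 1) iterate_cor[it] <- cor(prev, cur)
      prev <- cur
      if (it %in% c(1, ceiling(iters / 2), iters))
        snapshots[[length(snapshots) + 1]] <-
          list(iter = it, left = L[, , 1], right = R[, , 1])
    }
    sc <- max(abs(c(L, R)))
    pair <- stereo_pair(L[, , 1] / sc, R[, , 1] / sc, unit = unit,
                        note = "normalized for display")
    list(pair = pair, left = L[, , 1], right = R[, , 1],
         objective = objective, iterate_cor = iterate_cor,
         snapshots = snapshots)
  })
}

#' Depth-sign map of a large stereogram
#'
#' Applies the trained network convolutionally to an input of arbitrary
#' size: the rectified convolutional maps are combined with the mean
#' readout weight of each kernel for each output unit (plus the output
#' bias), giving one activity map per output; the map returned is the
#' element-wise difference far minus near, so positive values indicate
#' "far" (the convention is recorded in the attributes).
#'
#' @param model A trained 2-way [bnn_model()].
#' @param pair A [stereo_pair()] at least as large as the kernels.
#' @return A matrix of class `depth_sign_map` (input size minus kernel + 1),
#'   with attributes `positive` = "far" and `maps` (per-output maps).
#' @export
depth_sign_map <- function(model, pair) {
  stopifnot(inherits(model, "bnn_model"), inherits(pair, "stereo_pair"))
  if (model$n_outputs != 2) stop("depth-sign maps require a 2-way model")
  d <- dim(pair$left)
  kh <- model$kernel_size
  if (any(d < kh)) stop("input smaller than the kernels")
  L <- array(pair$left, c(d, 1)); R <- array(pair$right, c(d, 1))
  conv <- pmax(conv_forward(L, R, kernel_matrix(model), model$conv_bias), 0)
  pooled_per <- ncol(model$W) / model$n_kernels
  wbar <- vapply(seq_len(model$n_kernels), function(k) {
    cols <- (k - 1) * pooled_per + seq_len(pooled_per)
    rowMeans(model$W[, cols, drop = FALSE])
  }, numeric(model$n_outputs))                      # N x K
  oh <- d[1] - kh + 1
  maps <- lapply(seq_len(model$n_outputs), function(j) {
    matrix(conv %*% wbar[j, ] + model$b[j], oh)
  })
  names(maps) <- model$classes
  dsm <- maps[["far"]] - maps[["near"]]
  structure(dsm, class = c("depth_sign_map", "matrix"),
            positive = "far", maps = maps)
}

#' Excitatory/suppressive drive decomposition
#'
#' Splits each output unit's weighted readout of the pooled simple-unit
#' activity into the excitatory (positive-weight) and suppressive
#' (negative-weight) components; their sum reconstructs the pre-bias logit.
#'
#' @param model A trained [bnn_model()].
#' @param left,right Input patch batch (`(h, w, n)` arrays or matrices).
#' @return List with matrices `excitatory` and `suppressive` (n x N) and
#'   `logits` (n x N, bias included).
#' @export
drive_decomposition <- function(model, left, right) {
  fw <- bnn_forward(model, left, right, keep = "pooled")
  Wp <- pmax(model$W, 0); Wn <- pmin(model$W, 0)
  exc <- t(Wp %*% fw$pooled)
  sup <- t(Wn %*% fw$pooled)
  list(excitatory = exc, suppressive = sup, logits = fw$logits)
}
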