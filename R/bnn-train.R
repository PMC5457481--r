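#' Training configuration for the binocular network
#'
#' Defaults follow the reference training procedure: constant learning rate
#' 0.001, mini-batches of 100 examples (50 per class), at most 1,000 epochs,
#' and early stopping with an initial patience of 10,000 mini-batch updates
#' that doubles every time validation accuracy improves by at least 0.5
#' percentage points. "Iterations" in the patience rule are mini-batch
#' updates, not epochs; improvement is absolute percentage points of
#' validation accuracy.
#'
#' @param learning_rate Constant learning rate.
#' @param batch_size Examples per mini-batch (split evenly across classes).
#' @param max_epochs Maximum number of epochs.
#' @param patience Initial number of updates allowed without improvement.
#' @param patience_factor Multiplier applied to the patience on improvement.
#' @param improvement Validation-accuracy gain (percentage points) that
#'   counts as an improvement.
#' @param shuffle Reshuffle the training examples every epoch.
#' @param precision `"double"` (the reference arithmetic, used by all
#'   gradient verification) or `"single"`, which runs the two convolution
#'   GEMMs of each update in single precision (about twice the throughput
#'   on this memory-bound shape; round-off near 1e-7 is orders of magnitude
#'   below mini-batch gradient noise). Forward evaluation passes always use
#'   double precision.
#' @param seed Optional RNG seed for batch order.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 100,
                         max_epochs = 1000, patience = 10000,
                         patience_factor = 2, improvement = 0.5,
                         shuffle = TRUE, precision = c("double", "single"),
                         seed = NULL) {
  precision <- match.arg(precision)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 patience_factor = patience_factor, improvement = improvement,
                 shuffle = shuffle, precision = precision, seed = seed),
            class = "train_config")
}

# internal: cross-entropy loss and parameter gradients for one batch.
# Gradients are already averaged over the batch, matching the update rule
# w <- w - alpha * <dL/dw>.
bnn_gradients <- function(model, left, right, labels, precision = "double") {
  if (is.matrix(left)) left <- array(left, c(dim(left), 1))
  if (is.matrix(right)) right <- array(right, c(dim(right), 1))
  single <- identical(precision, "single")
  n <- dim(left)[3]; N <- model$n_outputs; K <- model$n_kernels
  kh <- model$kernel_size
  oh <- model$input_size - kh + 1
  conv_fun <- if (single) conv_forward_single else conv_forward
  conv <- pmax(conv_fun(left, right, kernel_matrix(model),
                        model$conv_bias), 0)
  pf <- pool_forward(conv, oh, oh, n, K)
  logits <- t(model$W %*% pf$pooled + model$b)
  probs <- softmax_rows(logits)
  y <- matrix(0, n, N)
  y[cbind(seq_len(n), as.integer(labels))] <- 1
  loss <- -mean(log(pmax(probs[y == 1], 1e-300)))
  dlogits <- (probs - y) / n                          # n x N
  dW <- dlogits_to_readout_grads(dlogits, pf$pooled)
  dpooled <- crossprod(model$W, t(dlogits))           # 1008 x n
  dconv <- pool_backward(dpooled, pf$idx, oh, oh, n, K)
  dconv[conv == 0] <- 0                               # ReLU gate
  bwd_fun <- if (single) conv_backward_kernels_single else
    conv_backward_kernels
  dk <- bwd_fun(left, right, dconv, kh, kh)
  list(loss = loss,
       grads = list(kernels = array(dk, dim(model$kernels)),
                    conv_bias = colSums(dconv),
                    W = dW$W, b = dW$b),
       probs = probs)
}

# internal
dlogits_to_readout_grads <- function(dlogits, pooled) {
  list(W = t(dlogits) %*% t(pooled), b = colSums(dlogits))
}

# internal: apply one gradient-descent step
bnn_update <- function(model, grads, lr) {
  model$kernels <- model$kernels - lr * grads$kernels
  model$conv_bias <- model$conv_bias - lr * grads$conv_bias
  model$W <- model$W - lr * grads$W
  model$b <- model$b - lr * grads$b
  model
}

# internal: accuracy (%) of the model on a patch set, evaluated in chunks
bnn_accuracy <- function(model, set, chunk = 500) {
  n <- dim(set$left)[3]
  correct <- 0
  for (s in seq(1, n, by = chunk)) {
    i <- s:min(s + chunk - 1, n)
    fw <- bnn_forward(model, set$left[, , i, drop = FALSE],
                      set$right[, , i, drop = FALSE])
    correct <- correct + sum(fw$pred == as.integer(set$label[i]))
  }
  100 * correct / n
}

#' Train the binocular network by mini-batch gradient descent
#'
#' Minimizes the categorical cross-entropy of the softmax readout with the
#' constant-learning-rate update `w <- w - alpha * <dL/dw>`, batches
#' balanced across classes. After every epoch the model is evaluated on the
#' validation set; training stops after `max_epochs` or when the number of
#' updates since the last validation improvement exceeds the (doubling)
#' patience. The model with the best validation accuracy is returned.
#'
#' @param model A [bnn_model()] (typically from [init_bnn()]).
#' @param train,val `patch_set`s with near/far labels (see
#'   [extract_patches()]).
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best-validation parameters), `history`
#'   (per-epoch data frame) and `final` (last-epoch model).
#' @export
bnn_train <- function(model, train, val, config = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(model, "bnn_model"), inherits(config, "train_config"))
  classes <- levels(train$label)
  if (length(classes) != model$n_outputs)
    stop("label classes must match the number of output units")
  model$classes <- classes
  per_class <- config$batch_size / length(classes)
  if (per_class != round(per_class))
    stop("batch_size must be divisible by the number of classes")
  class_idx <- lapply(seq_along(classes),
                      function(k) which(as.integer(train$label) == k))
  n_batches <- min(vapply(class_idx, length, 1L)) %/% per_class
  if (n_batches < 1) stop("not enough examples per class for one balanced batch")

  best <- list(acc = -Inf, model = model)
  patience <- config$patience
  updates <- 0; updates_at_best <- 0
  history <- vector("list", config$max_epochs)
  run <- function() {
    for (epoch in seq_len(config$max_epochs)) {
      order_idx <- lapply(class_idx,
                          function(ix) if (config$shuffle) sample(ix) else ix)
      epoch_loss <- 0
      for (bi in seq_len(n_batches)) {
        rows <- (bi - 1) * per_class + seq_len(per_class)
        batch <- unlist(lapply(order_idx, `[`, rows))
        g <- bnn_gradients(model,
                           train$left[, , batch, drop = FALSE],
                           train$right[, , batch, drop = FALSE],
                           train$label[batch], config$precision)
        model <<- bnn_update(model, g$grads, config$learning_rate)
        updates <<- updates + 1
        epoch_loss <- epoch_loss + g$loss
      }
      val_acc <- bnn_accuracy(model, val)
      if (val_acc >= best$acc + config$improvement) {
        patience <<- patience * config$patience_factor
      }
      if (val_acc > best$acc) {
        best <<- list(acc = val_acc, model = model)
        updates_at_best <<- updates
      }
      history[[epoch]] <<- data.frame(
        epoch = epoch, train_loss = epoch_loss / n_batches,
        val_acc = val_acc, patience = patience, updates = updates)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val %.2f%% (patience %d)",
                        epoch, epoch_loss / n_batches, val_acc, patience))
      if (updates - updates_at_best > patience) break
    }
  }
  with_seed_if(config$seed, run())
  best$model$meta$trained <- TRUE
  best$model$meta$val_acc <- best$acc
  best$model$meta$config <- config
  list(model = best$model, history = do.call(rbind, history), final = model)
}

#' Evaluate classification accuracy with a bootstrap confidence interval
#'
#' @param model A trained [bnn_model()].
#' @param set A `patch_set` with labels aligned to the model's classes.
#' @param n_boot Bootstrap resamples for the percentile CI.
#' @param seed Optional RNG seed for the resampling.
#' @return List with `accuracy` (%), `ci` (95% percentile interval), and the
#'   per-example correctness vector.
#' @export
bnn_evaluate <- function(model, set, n_boot = 1000, seed = NULL) {
  n <- dim(set$left)[3]
  correct <- logical(n)
  for (s in seq(1, n, by = 500)) {
    i <- s:min(s + 499, n)
    fw <- bnn_forward(model, set$left[, , i, drop = FALSE],
                      set$right[, , i, drop = FALSE])
    correct[i] <- fw$pred == as.integer(set$label[i])
  }
  boot <- with_seed_if(seed, {
    vapply(seq_len(n_boot),
           function(b) mean(correct[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  list(accuracy = 100 * mean(correct),
       ci = 100 * unname(quantile(boot, c(0.025, 0.975))),
       correct = correct)
}

#' Build a random-dot stereogram test set for the network
#'
#' Generates RDS patches at the network's input size with disparities drawn
#' from the supplied near/far values and labels them by disparity sign,
#' mirroring the laboratory test stimuli (1-px dots at 50% density, mixed
#' polarity on mid-gray, unless overridden).
#'
#' @param n Number of patches.
#' @param disparities Vector of signed disparities to draw from (near
#'   negative, far positive).
#' @param input_size Patch side, pixels.
#' @param correlation `"correlated"` or `"anticorrelated"`.
#' @param dot_size,density,polarity Dot parameters.
#' @param seed Optional RNG seed.
#' @return A `patch_set` (labels are the ground-truth disparity signs).
#' @export
make_rds_test_set <- function(n, disparities = c(-4, 4), input_size = 30,
                              correlation = c("correlated", "anticorrelated"),
                              dot_size = 1, density = 0.5,
                              polarity = "mixed", seed = NULL) {
  correlation <- match.arg(correlation)
  with_seed_if(seed, {
    d <- sample(disparities, n, replace = TRUE)
    left <- array(0, c(input_size, input_size, n))
    right <- array(0, c(input_size, input_size, n))
    for (i in seq_len(n)) {
      pair <- make_rds(rds_config(size = input_size, dot_size = dot_size,
                                  density = density, polarity = polarity,
                                  disparity = d[i], correlation = correlation))
      left[, , i] <- pair$left
      right[, , i] <- pair$right
    }
    structure(list(left = left, right = right,
                   label = factor(ifelse(d < 0, "near", "far"),
                                  levels = c("near", "far")),
                   disparity = d), class = "patch_set")
  })
}
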