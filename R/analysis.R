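#' Disparity tuning of the network's output (complex) units
#'
#' Measures each output unit's pre-softmax activity to random-dot
#' stereogram patches across a disparity grid (fresh stimuli per trial).
#'
#' @param model A trained [bnn_model()].
#' @param disparities Integer disparity grid, pixels.
#' @param trials Trials per disparity.
#' @param correlation `"correlated"` or `"anticorrelated"`.
#' @param density,dot_size,polarity Dot parameters.
#' @param seed Optional RNG seed.
#' @return A list of [tuning_curve()]s, one per output unit.
#' @export
bnn_complex_tuning <- function(model, disparities = -20:20, trials = 100,
                               correlation = c("correlated", "anticorrelated"),
                               density = 0.5, dot_size = 1,
                               polarity = "mixed", seed = NULL) {
  stopifnot(inherits(model, "bnn_model"))
  correlation <- match.arg(correlation)
  s <- model$input_size
  with_seed_if(seed, {
    resp <- array(NA_real_, c(trials, length(disparities), model$n_outputs))
    m <- max(abs(disparities))
    for (t in seq_len(trials)) {
      base <- paint_dot_field(s, s + 2 * m, dot_size, density, polarity, 0)
      L <- array(NA_real_, c(s, s, length(disparities)))
      R <- array(NA_real_, c(s, s, length(disparities)))
      for (k in seq_along(disparities)) {
        d <- disparities[k]
        L[, , k] <- base[, (m + 1):(m + s)]
        R[, , k] <- base[, (m + 1 - d):(m + s - d)] *
          (if (correlation == "anticorrelated") -1 else 1)
      }
      fw <- bnn_forward(model, L, R)
      resp[t, , ] <- fw$logits
    }
    lapply(seq_len(model$n_outputs), function(j) {
      tuning_curve(disparities, resp[, , j],
                   ensemble = list(correlation = correlation,
                                   unit = model$classes[j],
                                   density = density, dot_size = dot_size))
    })
  })
}

#' Bootstrap aRDS/cRDS amplitude-ratio distribution
#'
#' Resamples the per-disparity trials of a correlated and an anticorrelated
#' tuning curve with replacement, fits a Gabor (with DC offset) to each
#' resampled mean curve, and returns the distribution of the ratio of the
#' anticorrelated to the correlated fitted amplitude. The point fit's grid
#' search seeds the bootstrap fits. With `n_boot = 1` and no resampling
#' variation the result equals the point estimate.
#'
#' @param tc_correlated,tc_anticorrelated [tuning_curve()]s with per-trial
#'   responses on the same disparity grid.
#' @param n_boot Number of bootstrap resamples (5,000 to match the
#'   reference analysis).
#' @param r2_floor Resamples whose fit explains less variance than this in
#'   either condition are excluded (with a warning when more than 10% drop).
#' @param seed Optional RNG seed.
#' @return A list of class `amplitude_ratio_result`: `samples`, `point`
#'   (ratio of point fits), `r2_correlated`, `r2_anticorrelated` (mean
#'   bootstrap fit quality), `excluded`.
#' @export
amplitude_ratio <- function(tc_correlated, tc_anticorrelated, n_boot = 5000,
                            r2_floor = 0.2, seed = NULL) {
  stopifnot(inherits(tc_correlated, "tuning_curve"),
            inherits(tc_anticorrelated, "tuning_curve"))
  if (!identical(tc_correlated$disparity, tc_anticorrelated$disparity))
    stop("tuning curves must share one disparity grid")
  grid <- tc_correlated$disparity
  point_c <- fit_gabor_1d(tc_correlated$mean, grid, offset = TRUE)
  point_a <- fit_gabor_1d(tc_anticorrelated$mean, grid, offset = TRUE)
  refit <- function(y, init) {
    # bounded refinement seeded from the point fit (grid search done once)
    p0 <- c(init$params$amplitude, init$params$x0, init$params$sigma,
            init$params$freq, init$params$phase, init$offset)
    eval_g <- function(p) {
      d <- grid - p[2]
      p[1] * exp(-d^2 / (2 * p[3]^2)) * cos(2 * pi * p[4] * d + p[5]) + p[6]
    }
    rngd <- diff(range(grid))
    lower <- c(1e-10, min(grid), 0.2, max(init$params$freq * 0.5, 1e-4),
               -pi, -Inf)
    upper <- c(Inf, max(grid), 4 * rngd, init$params$freq * 2, pi, Inf)
    fit <- optim(pmin(pmax(p0, lower), upper),
                 function(p) sum((y - eval_g(p))^2),
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 200))
    sst <- sum((y - mean(y))^2)
    list(amplitude = fit$par[1],
         r2 = if (sst > 0) 1 - fit$value / sst else NA_real_)
  }
  nt_c <- nrow(tc_correlated$trials)
  nt_a <- nrow(tc_anticorrelated$trials)
  res <- with_seed_if(seed, {
    samples <- numeric(n_boot); r2c <- numeric(n_boot); r2a <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      yc <- colMeans(tc_correlated$trials[sample.int(nt_c, nt_c,
                                                     replace = TRUE), ,
                                          drop = FALSE])
      ya <- colMeans(tc_anticorrelated$trials[sample.int(nt_a, nt_a,
                                                         replace = TRUE), ,
                                              drop = FALSE])
      fc <- refit(yc, point_c); fa <- refit(ya, point_a)
      samples[b] <- fa$amplitude / fc$amplitude
      r2c[b] <- fc$r2; r2a[b] <- fa$r2
    }
    keep <- is.finite(samples) & r2c >= r2_floor & r2a >= r2_floor
    if (mean(!keep) > 0.1)
      warning(sprintf("%d/%d bootstrap fits excluded (poor fit quality)",
                      sum(!keep), n_boot))
    list(samples = samples[keep],
         point = point_a$params$amplitude / point_c$params$amplitude,
         r2_correlated = mean(r2c[keep]), r2_anticorrelated = mean(r2a[keep]),
         excluded = sum(!keep))
  })
  structure(res, class = "amplitude_ratio_result")
}

#' @export
print.amplitude_ratio_result <- function(x, ...) {
  cat(sprintf(paste0("Amplitude ratio (aRDS/cRDS): point %.3f, bootstrap ",
                     "median %.3f [%.3f, %.3f] (n = %d)\n"),
              x$point, median(x$samples),
              quantile(x$samples, 0.025), quantile(x$samples, 0.975),
              length(x$samples)))
  invisible(x)
}

#' Readout weights versus receptive-field cross-correlograms
#'
#' For each output unit, correlates the 28 kernels' mean readout weights
#' with the mean of each kernel's interocular cross-correlogram over that
#' output's preferred disparity range (near = negative lags, far = positive
#' lags).
#'
#' @param model A trained 2-way [bnn_model()].
#' @param lag_range Positive integer lags defining the near/far ranges
#'   (defaults to 1..half the kernel width).
#' @return Data frame with one row per output: `output`, `r`, `p`.
#' @export
readout_vs_crosscorr <- function(model, lag_range = NULL) {
  stopifnot(inherits(model, "bnn_model"))
  if (all(model$W == 0)) stop("readout weights are all zero (untrained model)")
  if (is.null(lag_range)) lag_range <- seq_len(model$kernel_size %/% 2)
  pooled_per <- ncol(model$W) / model$n_kernels
  wbar <- vapply(seq_len(model$n_kernels), function(k) {
    cols <- (k - 1) * pooled_per + seq_len(pooled_per)
    rowMeans(model$W[, cols, drop = FALSE])
  }, numeric(model$n_outputs))                       # N x K
  cc <- vapply(seq_len(model$n_kernels), function(k) {
    u <- bnn_unit_rf(model, k)
    c(near = mean(rf_cross_correlogram(u, -lag_range)),
      far = mean(rf_cross_correlogram(u, lag_range)))
  }, numeric(2))                                     # 2 x K
  rows <- lapply(seq_len(model$n_outputs), function(j) {
    side <- if (model$classes[j] == "near") "near" else "far"
    ct <- cor.test(wbar[j, ], cc[side, ])
    data.frame(output = model$classes[j], r = unname(ct$estimate),
               p = ct$p.value)
  })
  do.call(rbind, rows)
}

# internal: choose the step arrangement from a signed depth map.
# `map` uses positive = far. Returns "left" or "right" = the near side.
step_decision_from_map <- function(map) {
  nc <- ncol(map)
  left <- mean(map[, seq_len(nc %/% 2)])
  right <- mean(map[, (nc %/% 2 + 1):nc])
  if (left < right) "left" else "right"
}

#' Step-arrangement discrimination across dot-polarity conditions
#'
#' On each trial a fresh step-edge stereogram (random arrangement) is
#' generated, optionally passed through a luminance control, and judged
#' from the model's depth-sign map: the half with the lower (nearer) mean
#' map value is reported as the near side. Proportion correct is returned
#' per polarity condition and control. With `oracle = TRUE` the decision
#' rule is applied to the ground-truth disparity map instead of the model
#' (separating decision-rule error from model error).
#'
#' @param model A trained 2-way [bnn_model()] (ignored when
#'   `oracle = TRUE`).
#' @param n_trials Trials per condition/control cell.
#' @param polarities Dot polarity conditions.
#' @param controls Luminance controls (`"none"` plus any
#'   [polarity_controls()] mode).
#' @param config A [step_edge_config()] template (polarity, near side and
#'   seed fields are overridden per trial).
#' @param oracle Use the ground-truth per-dot disparities for the decision.
#' @param paired If `TRUE`, one dot layout (geometry, disparity noise and
#'   arrangement) is generated per trial and re-rendered at every polarity,
#'   so condition comparisons share the same stimulus noise (a paired
#'   design; greatly reduces the variance of between-polarity contrasts).
#' @param seed Master RNG seed.
#' @return Data frame of class `polarity_task_result`: `polarity`,
#'   `control`, `prop_correct`, `n_trials`.
#' @export
polarity_task <- function(model, n_trials = 1000,
                          polarities = c("mixed", "bright", "dark"),
                          controls = "none",
                          config = step_edge_config(), oracle = FALSE,
                          paired = FALSE, seed = NULL) {
  judge <- function(pair, ctl, cfg) {
    if (oracle) {
      gt <- matrix(0, cfg$size[1], cfg$size[2])
      dots <- pair$meta$dots
      for (i in seq_len(nrow(dots))) {
        rr <- dots$row[i]:(dots$row[i] + cfg$dot_size - 1)
        cc <- dots$col[i]:(dots$col[i] + cfg$dot_size - 1)
        gt[rr, cc] <- dots$disparity[i]
      }
      return(step_decision_from_map(gt))
    }
    if (ctl != "none") pair <- polarity_controls(pair, ctl)
    step_decision_from_map(depth_sign_map(model, pair))
  }
  cells <- expand.grid(polarity = polarities, control = controls,
                       stringsAsFactors = FALSE)
  pc <- with_seed_if(seed, {
    if (paired) {
      hits <- matrix(0, nrow(cells), n_trials)
      for (t in seq_len(n_trials)) {
        cfg <- config
        cfg$polarity <- "mixed"
        cfg$near_side <- sample(c("left", "right"), 1)
        cfg$seed <- NULL
        base <- make_step_edge(cfg)
        for (i in seq_len(nrow(cells))) {
          dots <- repolarize_dots(base$meta$dots, cells$polarity[i])
          pair <- paint_step_pair(dots, cfg$size[1], cfg$size[2],
                                  cfg$dot_size, cfg)
          hits[i, t] <- judge(pair, cells$control[i], cfg) == cfg$near_side
        }
      }
      rowMeans(hits)
    } else {
      vapply(seq_len(nrow(cells)), function(i) {
        correct <- logical(n_trials)
        for (t in seq_len(n_trials)) {
          cfg <- config
          cfg$polarity <- cells$polarity[i]
          cfg$near_side <- sample(c("left", "right"), 1)
          cfg$seed <- NULL
          pair <- make_step_edge(cfg)
          correct[t] <- judge(pair, cells$control[i], cfg) == cfg$near_side
        }
        mean(correct)
      }, numeric(1))
    }
  })
  structure(data.frame(cells, prop_correct = pc, n_trials = n_trials),
            class = c("polarity_task_result", "data.frame"))
}
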