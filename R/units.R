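#' Output nonlinearity of a simple unit
#'
#' @param kind One of `"relu"` (half-wave rectification), `"squaring"`
#'   (unrectified `x^2`), `"rectified-squaring"` (`max(x, 0)^2`), or
#'   `"power"` (rectified power `max(x, 0)^exponent`).
#' @param exponent Exponent for the `"power"` kind (> 0).
#' @return An object of class `nonlinearity`; apply it with
#'   [apply_nonlinearity()].
#' @export
nonlinearity <- function(kind = c("relu", "squaring", "rectified-squaring",
                                  "power"), exponent = 2) {
  kind <- match.arg(kind)
  if (kind == "power" && exponent <= 0) stop("exponent must be > 0")
  structure(list(kind = kind, exponent = exponent), class = "nonlinearity")
}

#' @param x Numeric vector/matrix of linear drives.
#' @param nl A [nonlinearity()].
#' @rdname nonlinearity
#' @export
apply_nonlinearity <- function(x, nl) {
  stopifnot(inherits(nl, "nonlinearity"))
  switch(nl$kind,
         relu = pmax(x, 0),
         squaring = x^2,
         `rectified-squaring` = pmax(x, 0)^2,
         power = pmax(x, 0)^nl$exponent)
}

#' Simple-unit response to a stereo pair
#'
#' Computes `g(W_L . s_L + W_R . s_R + b)`. In `"single"` mode the stimulus
#' must match the receptive-field size and a scalar rate is returned; in
#' `"map"` mode the field is applied convolutionally at all valid positions
#' (no padding) and a response map is returned.
#'
#' @param rf A [binocular_rf()].
#' @param pair A [stereo_pair()].
#' @param nl A [nonlinearity()].
#' @param mode `"single"` or `"map"`.
#' @return Scalar rate or response-map matrix.
#' @export
simple_response <- function(rf, pair, nl = nonlinearity("rectified-squaring"),
                            mode = c("single", "map")) {
  stopifnot(inherits(rf, "binocular_rf"), inherits(pair, "stereo_pair"))
  mode <- match.arg(mode)
  if (mode == "single") {
    if (!identical(dim(rf$wl), dim(pair$left)))
      stop("stimulus shape must match the receptive field in single mode")
    drive <- sum(rf$wl * pair$left) + sum(rf$wr * pair$right) + rf$bias
    apply_nonlinearity(drive, nl)
  } else {
    kh <- nrow(rf$wl); kw <- ncol(rf$wl)
    L <- array(pair$left, c(dim(pair$left), 1))
    R <- array(pair$right, c(dim(pair$right), 1))
    X <- stereo_im2col(L, R, kh, kw)
    drive <- X %*% c(rf$wl, rf$wr) + rf$bias
    oh <- nrow(pair$left) - kh + 1
    matrix(apply_nonlinearity(drive, nl), oh)
  }
}

#' Disparity tuning curve container
#'
#' @param disparity Strictly increasing disparity grid, pixels.
#' @param trials Matrix of per-trial responses (trials x disparities).
#' @param ensemble Optional description of the stimulus ensemble.
#' @return A `tuning_curve`: list with `disparity`, `mean`, `sd`, `trials`,
#'   `ensemble`.
#' @export
tuning_curve <- function(disparity, trials, ensemble = NULL) {
  trials <- as.matrix(trials)
  if (any(diff(disparity) <= 0)) stop("disparity grid must be increasing")
  if (ncol(trials) != length(disparity))
    stop("trials must have one column per disparity")
  structure(list(disparity = disparity, mean = colMeans(trials),
                 sd = apply(trials, 2, sd), trials = trials,
                 ensemble = ensemble),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("Tuning curve: %d disparities in [%g, %g] px, %d trials; peak at %g px\n",
              length(x$disparity), min(x$disparity), max(x$disparity),
              nrow(x$trials), x$disparity[which.max(x$mean)]))
  invisible(x)
}

#' Export a tuning curve to CSV
#'
#' @param tc A [tuning_curve()].
#' @param path Output path.
#' @return The data frame, invisibly.
#' @export
write_tuning_csv <- function(tc, path) {
  out <- data.frame(disparity = tc$disparity, mean = tc$mean, sd = tc$sd,
                    n = nrow(tc$trials))
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Empirical disparity tuning of a simple unit
#'
#' Responds to fresh random-dot (or uniform-noise) stereograms at each
#' disparity on the grid. All disparities within a trial share the same base
#' image (the right-eye crop slides across it), which removes between-lag
#' sampling noise.
#'
#' @param rf A [binocular_rf()].
#' @param nl A [nonlinearity()].
#' @param disparities Disparity grid, pixels (integers).
#' @param trials Trials per disparity (>= 1).
#' @param stim `"rds"` (mixed-polarity dots) or `"uniform"` (i.i.d. uniform
#'   intensities in `[-1, 1]`).
#' @param density,dot_size RDS parameters.
#' @param correlation `"correlated"` or `"anticorrelated"`.
#' @param seed Optional RNG seed.
#' @return A [tuning_curve()].
#' @export
disparity_tuning <- function(rf, nl = nonlinearity("rectified-squaring"),
                             disparities = -20:20, trials = 100,
                             stim = c("rds", "uniform"), density = 0.5,
                             dot_size = 1,
                             correlation = c("correlated", "anticorrelated"),
                             seed = NULL) {
  stopifnot(inherits(rf, "binocular_rf"), trials >= 1)
  stim <- match.arg(stim)
  correlation <- match.arg(correlation)
  disparities <- as.integer(disparities)
  h <- nrow(rf$wl); w <- ncol(rf$wl)
  m <- max(abs(disparities))
  wl <- c(rf$wl); wr <- c(rf$wr)
  anti <- if (correlation == "anticorrelated") -1 else 1
  with_seed_if(seed, {
    resp <- matrix(NA_real_, trials, length(disparities))
    base_w <- w + 2 * m
    for (t in seq_len(trials)) {
      base <- if (stim == "uniform") {
        matrix(runif(h * base_w, -1, 1), h, base_w)
      } else {
        paint_dot_field(h, base_w, dot_size, density, "mixed", 0)
      }
      left <- base[, (m + 1):(m + w), drop = FALSE]
      dl <- sum(wl * left)
      for (k in seq_along(disparities)) {
        d <- disparities[k]
        right <- base[, (m + 1 - d):(m + w - d), drop = FALSE]
        resp[t, k] <- apply_nonlinearity(dl + anti * sum(wr * right) + rf$bias, nl)
      }
    }
    tuning_curve(disparities, resp,
                 ensemble = list(stim = stim, density = density,
                                 dot_size = dot_size, correlation = correlation,
                                 trials = trials))
  })
}

#' Interocular receptive-field cross-correlogram
#'
#' `c[d] = sum_{x,y} W_L(y, x) * W_R(y, x + d)`, with samples outside the
#' grid treated as zero. Under the package's disparity convention a unit
#' whose right-eye field is the left one translated by `+d` pixels peaks at
#' lag `+d`, which is also its preferred stimulus disparity; positive lobes
#' act as excitatory (detection) evidence and negative lobes as suppressive
#' (proscription) evidence in the likelihood readout.
#'
#' @param rf A [binocular_rf()].
#' @param lags Integer lag grid; defaults to +/- the field half-width.
#' @return Named numeric vector of correlogram values per lag.
#' @export
rf_cross_correlogram <- function(rf, lags = NULL) {
  stopifnot(inherits(rf, "binocular_rf"))
  w <- ncol(rf$wl)
  if (is.null(lags)) lags <- -floor(w / 2):floor(w / 2)
  lags <- as.integer(lags)
  if (any(abs(lags) >= w)) stop("lags must be within the RF width")
  vals <- vapply(lags, function(d) {
    xl <- max(1, 1 - d):min(w, w - d)
    sum(rf$wl[, xl, drop = FALSE] * rf$wr[, xl + d, drop = FALSE])
  }, numeric(1))
  names(vals) <- lags
  vals
}

#' Cross-correlogram prediction of a disparity tuning curve
#'
#' For a squaring nonlinearity the expected tuning curve over broadband
#' stimuli is `f(d) = 2 (W_L x W_R)[d] E(S^2) + C`, where `E(S^2)` is the
#' mean per-pixel stimulus energy and `C` the disparity-independent sum of
#' the two monocular energy terms. Both scalars are estimated from data:
#' pass the stimulus energy of the ensemble and a fitted constant, or use
#' [fit_tuning_prediction()] to estimate them from an empirical curve.
#'
#' @param rf A [binocular_rf()].
#' @param lags Integer lag grid.
#' @param energy Mean per-pixel stimulus energy `E(S^2)`.
#' @param constant Disparity-independent offset `C`.
#' @return Numeric vector of predicted mean responses per lag.
#' @export
predict_tuning_from_rf <- function(rf, lags, energy = 1, constant = 0) {
  2 * rf_cross_correlogram(rf, lags) * energy + constant
}

#' Fit the affine scaling of the cross-correlogram prediction
#'
#' Estimates `E(S^2)` and `C` by least squares from an empirical tuning
#' curve, returning the calibrated prediction and the Pearson correlation
#' between prediction and measurement.
#'
#' @param rf A [binocular_rf()].
#' @param tc A [tuning_curve()] measured with a squaring nonlinearity.
#' @return List with `energy`, `constant`, `predicted`, `r`.
#' @export
fit_tuning_prediction <- function(rf, tc) {
  cc <- 2 * rf_cross_correlogram(rf, tc$disparity)
  fit <- stats::lm.fit(cbind(cc, 1), tc$mean)
  list(energy = fit$coefficients[1], constant = fit$coefficients[2],
       predicted = cc * fit$coefficients[1] + fit$coefficients[2],
       r = cor(cc, tc$mean))
}
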