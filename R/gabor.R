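#' Gabor receptive-field parameters
#'
#' Container for the parameters of a one-dimensional Gabor function
#' `A * exp(-(x - x0)^2 / (2 sigma^2)) * cos(2 pi f (x - x0) + phi)`.
#' For two-dimensional receptive fields the same parameters are extended with
#' an orientation `theta` (radians, `theta = pi/2` gives the vertically
#' oriented fields used throughout) and a vertical center `y0`.
#'
#' @param amplitude Response amplitude `A` (>= 0).
#' @param x0 Horizontal center of the envelope, pixels.
#' @param sigma Gaussian envelope width, pixels (> 0).
#' @param freq Spatial frequency, cycles/pixel (> 0).
#' @param phase Carrier phase, radians; wrapped into `[-pi, pi)`.
#' @param theta Orientation, radians in `[0, pi)`; only for 2-D fields.
#' @param y0 Vertical center, pixels; only for 2-D fields.
#' @return An object of class `gabor_params`.
#' @seealso [make_gabor_1d()], [make_gabor_2d()], [fit_gabor_1d()]
#' @export
gabor_params <- function(amplitude = 1, x0 = 0, sigma, freq, phase = 0,
                         theta = NULL, y0 = NULL) {
  stopifnot(is.numeric(amplitude), is.numeric(x0), is.numeric(sigma),
            is.numeric(freq), is.numeric(phase))
  if (sigma <= 0) stop("sigma must be > 0")
  if (freq <= 0) stop("freq must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  p <- list(amplitude = amplitude, x0 = x0, sigma = sigma, freq = freq,
            phase = wrap_phase(phase))
  if (!is.null(theta)) {
    p$theta <- theta %% pi
    p$y0 <- if (is.null(y0)) 0 else y0
  }
  structure(p, class = "gabor_params")
}

#' @export
print.gabor_params <- function(x, ...) {
  cat(sprintf("Gabor: A=%.4g x0=%.3g sigma=%.3g f=%.4g cyc/px phase=%.3f rad",
              x$amplitude, x$x0, x$sigma, x$freq, x$phase))
  if (!is.null(x$theta)) cat(sprintf(" theta=%.3f y0=%.3g", x$theta, x$y0))
  cat("\n")
  invisible(x)
}

#' Evaluate a one-dimensional Gabor profile
#'
#' @param params A [gabor_params()] object.
#' @param grid Monotone numeric vector of pixel coordinates.
#' @return Numeric vector of the profile evaluated on `grid`.
#' @export
make_gabor_1d <- function(params, grid) {
  stopifnot(inherits(params, "gabor_params"))
  if (!is.numeric(grid) || anyNA(grid) || any(diff(grid) <= 0))
    stop("grid must be a finite monotone increasing coordinate vector")
  d <- grid - params$x0
  params$amplitude * exp(-d^2 / (2 * params$sigma^2)) *
    cos(2 * pi * params$freq * d + params$phase)
}

#' Evaluate a two-dimensional oriented Gabor on a pixel grid
#'
#' The carrier axis is defined so that `theta = pi/2` produces a vertically
#' oriented field (carrier varying along x, stripes running vertically), the
#' configuration used by all binocular models in this package.
#'
#' @param params A [gabor_params()] with `theta` set.
#' @param nrow,ncol Grid size in pixels; centered integer coordinates.
#' @return A `nrow` x `ncol` matrix.
#' @export
make_gabor_2d <- function(params, nrow, ncol) {
  stopifnot(inherits(params, "gabor_params"))
  theta <- if (is.null(params$theta)) pi / 2 else params$theta
  y0 <- if (is.null(params$y0)) 0 else params$y0
  x <- matrix(pixel_grid(ncol), nrow, ncol, byrow = TRUE) - params$x0
  y <- matrix(pixel_grid(nrow), nrow, ncol) - y0
  xc <- x * sin(theta) + y * cos(theta)   # carrier axis
  yc <- -x * cos(theta) + y * sin(theta)
  params$amplitude * exp(-(xc^2 + yc^2) / (2 * params$sigma^2)) *
    cos(2 * pi * params$freq * xc + params$phase)
}

#' Binocular receptive field
#'
#' A simple unit's model: a left/right pair of 2-D filter weight grids of
#' identical shape plus a scalar bias.
#'
#' @param wl,wr Left- and right-eye weight matrices (identical shape).
#' @param bias Scalar bias, response units.
#' @param params_left,params_right Optional fitted/constructed
#'   [gabor_params()] per eye.
#' @return An object of class `binocular_rf`.
#' @export
binocular_rf <- function(wl, wr, bias = 0, params_left = NULL,
                         params_right = NULL) {
  wl <- as.matrix(wl); wr <- as.matrix(wr)
  if (!identical(dim(wl), dim(wr))) stop("left/right weights must match in shape")
  if (!all(is.finite(wl)) || !all(is.finite(wr)) || !is.finite(bias))
    stop("weights and bias must be finite")
  structure(list(wl = wl, wr = wr, bias = bias,
                 params_left = params_left, params_right = params_right),
            class = "binocular_rf")
}

#' @export
print.binocular_rf <- function(x, ...) {
  cat(sprintf("Binocular RF: %d x %d per eye, bias %.4g\n",
              nrow(x$wl), ncol(x$wl), x$bias))
  invisible(x)
}

#' Construct a binocular Gabor receptive field with position/phase disparity
#'
#' The left eye uses the base parameters `(x0, phase)`; the right eye uses
#' `(x0 + dx0, phase + dphi)`. All other parameters are shared, so `dx0`
#' implements pure position encoding, `dphi` pure phase encoding, and both
#' together hybrid encoding.
#'
#' @param base A [gabor_params()] (2-D; `theta` defaults to `pi/2`).
#' @param dx0 Position disparity, pixels (right minus left center).
#' @param dphi Phase disparity, radians (right minus left).
#' @param shape Integer vector `c(nrow, ncol)` of the weight grids.
#' @param bias Scalar bias.
#' @return A [binocular_rf()].
#' @export
make_binocular_gabor <- function(base, dx0 = 0, dphi = 0, shape, bias = 0) {
  stopifnot(inherits(base, "gabor_params"), length(shape) == 2)
  if (3 * base$sigma > min(shape) / 2)
    warning("envelope (3 sigma) exceeds half the grid width; field is truncated")
  if (is.null(base$theta)) base$theta <- pi / 2
  left <- base
  right <- base
  right$x0 <- base$x0 + dx0
  right$phase <- wrap_phase(base$phase + dphi)
  binocular_rf(make_gabor_2d(left, shape[1], shape[2]),
               make_gabor_2d(right, shape[1], shape[2]),
               bias = bias, params_left = left, params_right = right)
}

#' Gabor octave-bandwidth relation
#'
#' Convert between the envelope width of a Gabor and its spatial-frequency
#' bandwidth in octaves (full width at half maximum of the amplitude
#' spectrum): `sigma = (1/(pi f)) * sqrt(ln 2 / 2) * (2^b + 1)/(2^b - 1)`.
#'
#' @param freq Spatial frequency, cycles/pixel (> 0).
#' @param bandwidth Bandwidth in octaves (> 0).
#' @return `sigma_from_bandwidth` returns the envelope width in pixels;
#'   `bandwidth_octaves` the bandwidth in octaves (NaN, with a warning, when
#'   `sigma * pi * f` is too small for a real-valued solution).
#' @examples
#' sigma_from_bandwidth(0.0625, 1.5)   # ~6.27 px
#' @export
sigma_from_bandwidth <- function(freq, bandwidth) {
  if (any(freq <= 0)) stop("freq must be > 0")
  if (any(bandwidth <= 0)) stop("bandwidth must be > 0")
  (1 / (pi * freq)) * sqrt(log(2) / 2) *
    (2^bandwidth + 1) / (2^bandwidth - 1)
}

#' @param sigma Envelope width, pixels (> 0).
#' @rdname sigma_from_bandwidth
#' @export
bandwidth_octaves <- function(freq, sigma) {
  if (any(freq <= 0)) stop("freq must be > 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  r <- sigma * pi * freq / sqrt(log(2) / 2)
  b <- ifelse(r > 1, log2((r + 1) / (r - 1)), NaN)
  if (anyNA(b))
    warning("bandwidth undefined (envelope narrower than one carrier cycle); NaN returned")
  b
}

#' Non-parametric spectral bandwidth of a Gabor
#'
#' Synthesizes the Gabor's quadrature (analytic-signal) profile on a long,
#' finely sampled grid, computes its amplitude spectrum by FFT, and
#' measures the full width at half maximum in octaves. The quadrature pair
#' isolates the positive-frequency lobe, so the measurement is an
#' independent numerical check of the parametric [bandwidth_octaves()]
#' relation across the full range of physiological bandwidths.
#'
#' @param params A [gabor_params()].
#' @param oversample Sampling density relative to 1 px.
#' @param width_sigmas Half-width of the synthesis window in units of sigma.
#' @return Bandwidth in octaves.
#' @export
gabor_bandwidth_fft <- function(params, oversample = 8, width_sigmas = 12) {
  stopifnot(inherits(params, "gabor_params"))
  half <- max(width_sigmas * params$sigma, 4 / params$freq)
  dx <- 1 / oversample
  grid <- seq(-half, half, by = dx) + params$x0
  quad <- params
  quad$phase <- wrap_phase(params$phase - pi / 2)
  prof <- complex(real = make_gabor_1d(params, grid),
                  imaginary = make_gabor_1d(quad, grid))
  n <- length(prof)
  amp <- Mod(fft(prof))[seq_len(floor(n / 2))]
  fr <- (seq_len(floor(n / 2)) - 1) / (n * dx)
  spectrum_fwhm_octaves(fr, amp)
}

# internal: FWHM of a single-peaked spectrum, in octaves, by linear
# interpolation of the half-maximum crossings
spectrum_fwhm_octaves <- function(freqs, amp, floor_level = 0) {
  i <- which.max(amp)
  half <- floor_level + (max(amp) - floor_level) / 2
  lo <- NA_real_; hi <- NA_real_
  if (i > 1) {
    below <- which(amp[seq_len(i - 1)] < half)
    if (length(below)) {
      j <- max(below)
      lo <- approx(amp[c(j, j + 1)], freqs[c(j, j + 1)], xout = half)$y
    }
  }
  if (i < length(amp)) {
    below <- which(amp[seq(i + 1, length(amp))] < half) + i
    if (length(below)) {
      j <- min(below)
      hi <- approx(amp[c(j - 1, j)], freqs[c(j - 1, j)], xout = half)$y
    }
  }
  if (is.na(lo) || is.na(hi) || lo <= 0) return(NaN)
  log2(hi / lo)
}

# internal: peak frequency (cycles/px) of a profile's amplitude spectrum,
# excluding DC, refined by parabolic interpolation
fft_peak_freq <- function(profile, pad = 8) {
  n <- length(profile)
  m <- pad * n
  amp <- Mod(fft(c(profile - mean(profile), numeric(m - n))))
  half <- floor(m / 2)
  amp <- amp[2:half]
  k <- which.max(amp) + 1          # 1-based index into full spectrum
  (k - 1) / m
}

#' Fit a one-dimensional Gabor to a response profile
#'
#' Two-stage procedure: a coarse grid search over center, envelope width,
#' frequency and phase (with the amplitude solved in closed form at each grid
#' point) selects initial values; bound-constrained minimization (L-BFGS-B)
#' then refines them. Constraints follow the standard recipe: `0 < A`,
#' `min(x) < x0 < max(x)`, `-pi < phase < pi`, and the frequency restricted
#' to +/-10% around the peak of the profile's Fourier transform.
#'
#' @param profile Numeric vector of responses (length >= 8).
#' @param grid Pixel coordinates; defaults to centered integer pixels.
#' @param offset If `TRUE`, an additive DC offset is fitted alongside the
#'   Gabor (used for disparity tuning curves, which ride on a monocular
#'   baseline); RF profiles are fitted without one.
#' @param control List of grid-search resolutions:
#'   `n_phase`, `n_center`, `n_sigma`, `n_freq`.
#' @return A list with elements `params` ([gabor_params()]), `offset`,
#'   `r2` (explained variance), and `fitted`.
#' @export
fit_gabor_1d <- function(profile, grid = NULL, offset = FALSE,
                         control = list()) {
  profile <- as.numeric(profile)
  if (length(profile) < 8) stop("profile must have length >= 8")
  if (all(profile == 0)) stop("degenerate input: all-zero profile")
  if (is.null(grid)) grid <- pixel_grid(length(profile))
  ctl <- modifyList(list(n_phase = 12, n_center = 12, n_sigma = 8,
                         n_freq = 8), control)
  rng <- diff(range(grid))
  fpk <- fft_peak_freq(profile)
  fpk <- max(fpk, 1 / (2 * rng))   # guard degenerate spectra
  f_lo <- 0.9 * fpk; f_hi <- 1.1 * fpk

  centers <- seq(min(grid), max(grid), length.out = ctl$n_center)
  sigmas <- exp(seq(log(max(rng / 40, 0.5)), log(rng / 2),
                    length.out = ctl$n_sigma))
  freqs <- seq(f_lo, f_hi, length.out = ctl$n_freq)
  phases <- seq(-pi, pi, length.out = ctl$n_phase + 1)[seq_len(ctl$n_phase)]

  y <- profile
  best <- NULL; best_sse <- Inf
  for (x0 in centers) {
    d <- grid - x0
    env_all <- outer(d^2, -1 / (2 * sigmas^2))   # len x n_sigma of exponents
    env_all <- exp(env_all)
    for (fi in seq_along(freqs)) {
      ang <- 2 * pi * freqs[fi] * d
      for (ph in phases) {
        carrier <- cos(ang + ph)
        G <- env_all * carrier                    # len x n_sigma
        if (offset) {
          gg <- colSums(G * G); gs <- colSums(G); gy <- colSums(G * y)
          n <- length(y); sy <- sum(y)
          det <- gg * n - gs^2
          a <- (gy * n - gs * sy) / det
          c0 <- (sy - a * gs) / n
          sse <- sum(y^2) - 2 * a * gy - 2 * c0 * sy +
            a^2 * gg + 2 * a * c0 * gs + n * c0^2
        } else {
          gg <- colSums(G * G); gy <- colSums(G * y)
          a <- gy / pmax(gg, 1e-12)
          c0 <- numeric(length(a))
          sse <- sum(y^2) - a^2 * pmax(gg, 1e-12)
        }
        k <- which.min(sse)
        if (sse[k] < best_sse) {
          best_sse <- sse[k]
          best <- c(A = a[k], x0 = x0, sigma = sigmas[k],
                    f = freqs[fi], phi = ph, C = c0[k])
        }
      }
    }
  }
  if (best[["A"]] < 0) {   # fold a negative amplitude into the phase
    best[["A"]] <- -best[["A"]]
    best[["phi"]] <- wrap_phase(best[["phi"]] + pi)
  }

  eval_gabor <- function(p) {
    d <- grid - p[2]
    p[1] * exp(-d^2 / (2 * p[3]^2)) * cos(2 * pi * p[4] * d + p[5]) +
      if (offset) p[6] else 0
  }
  objective <- function(p) sum((y - eval_gabor(p))^2)
  par0 <- best[seq_len(if (offset) 6 else 5)]
  eps <- 1e-8
  lower <- c(1e-10, min(grid) + eps, 0.2, f_lo, -pi + eps,
             if (offset) -Inf)
  upper <- c(Inf, max(grid) - eps, 4 * rng, f_hi, pi - eps,
             if (offset) Inf)
  par0 <- pmin(pmax(par0, lower), upper)
  fit <- optim(par0, objective, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = 500))
  p <- unname(fit$par)
  fitted <- eval_gabor(p)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum((y - fitted)^2) / sst else NA_real_
  list(params = gabor_params(amplitude = p[1], x0 = p[2], sigma = p[3],
                             freq = p[4], phase = p[5]),
       offset = if (offset) p[6] else 0,
       r2 = r2, fitted = fitted, converged = fit$convergence == 0)
}

#' Classify the disparity encoding of a binocular receptive field
#'
#' Fits 1-D Gabors to the horizontal cross-sections of the two eyes' weight
#' grids (taken through the row of peak combined filter energy) and reports
#' the right-minus-left position and phase differences. Phase disparity is
#' wrapped to `[-pi, pi)`. A unit whose cross-sections are poorly fit
#' (either eye's R-squared below `r2_floor`) is flagged and should be
#' excluded from population summaries.
#'
#' @param rf A [binocular_rf()].
#' @param r2_floor Minimum per-eye explained variance (default 0.5).
#' @return A list of class `encoding_description` with `dx0` (pixels), `dphi`
#'   (radians), `r2_left`, `r2_right`, `ok`, and the per-eye fits.
#' @export
classify_encoding <- function(rf, r2_floor = 0.5) {
  stopifnot(inherits(rf, "binocular_rf"))
  energy <- rowSums(rf$wl^2 + rf$wr^2)
  row <- which.max(energy)
  grid <- pixel_grid(ncol(rf$wl))
  fit_eye <- function(w) {
    tryCatch(fit_gabor_1d(w[row, ], grid), error = function(e) NULL)
  }
  fl <- fit_eye(rf$wl); fr <- fit_eye(rf$wr)
  ok <- !is.null(fl) && !is.null(fr) &&
    isTRUE(fl$r2 >= r2_floor) && isTRUE(fr$r2 >= r2_floor)
  structure(list(
    dx0 = if (ok) fr$params$x0 - fl$params$x0 else NA_real_,
    dphi = if (ok) wrap_phase(fr$params$phase - fl$params$phase) else NA_real_,
    r2_left = if (is.null(fl)) NA_real_ else fl$r2,
    r2_right = if (is.null(fr)) NA_real_ else fr$r2,
    ok = ok, fit_left = fl, fit_right = fr, row = row
  ), class = "encoding_description")
}

#' @export
print.encoding_description <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("Encoding: dx0 = %.3f px, dphi = %.3f rad (R2 L/R %.3f/%.3f)\n",
                x$dx0, x$dphi, x$r2_left, x$r2_right))
  } else {
    cat("Encoding: fit below quality floor; unit flagged for exclusion\n")
  }
  invisible(x)
}

#' Export fitted receptive-field parameters to CSV
#'
#' One row per unit per eye: amplitude, center, sigma, frequency, phase and
#' fit R-squared.
#'
#' @param rfs List of [binocular_rf()] objects (with encodings computed) or a
#'   list of [classify_encoding()] results.
#' @param path Output CSV path.
#' @return The data frame, invisibly.
#' @export
write_rf_params_csv <- function(rfs, path) {
  rows <- lapply(seq_along(rfs), function(i) {
    enc <- if (inherits(rfs[[i]], "encoding_description")) rfs[[i]]
           else classify_encoding(rfs[[i]])
    eye_row <- function(eye, fit, r2) {
      p <- if (is.null(fit)) list(amplitude = NA, x0 = NA, sigma = NA,
                                  freq = NA, phase = NA) else fit$params
      data.frame(unit = i, eye = eye, amplitude = p$amplitude, x0 = p$x0,
                 sigma = p$sigma, freq = p$freq, phase = p$phase, r2 = r2)
    }
    rbind(eye_row("left", enc$fit_left, enc$r2_left),
          eye_row("right", enc$fit_right, enc$r2_right))
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
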