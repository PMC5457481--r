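#' Cross-correlogram readout weights for the binocular likelihood model
#'
#' The log likelihood of stimulus disparity is approximated by a weighted
#' sum of simple-unit firing rates in which the weight of unit i onto the
#' complex unit preferring disparity d equals the unit's interocular
#' receptive-field cross-correlogram at lag d. Positive correlogram lobes
#' act as excitation (detection), negative lobes as suppression
#' (proscription).
#'
#' @param bank List of [binocular_rf()] simple units.
#' @param lags Integer disparity grid for the readout, pixels.
#' @param nl The simple units' output [nonlinearity()].
#' @param sigma Optional per-unit response-noise scales (assumed equal, and
#'   dropped from the simplified readout, when `NULL`).
#' @return An object of class `likelihood_readout`: `bank`, `lags`,
#'   `weights` (units x lags, rows are the cross-correlograms), `nl`,
#'   `sigma`.
#' @export
blm_readout <- function(bank, lags = -20:20,
                        nl = nonlinearity("rectified-squaring"),
                        sigma = NULL) {
  if (inherits(bank, "binocular_rf")) bank <- list(bank)
  if (length(bank) == 0) stop("bank must be non-empty")
  weights <- t(vapply(bank, rf_cross_correlogram, numeric(length(lags)),
                      lags = lags))
  structure(list(bank = bank, lags = lags, weights = weights, nl = nl,
                 sigma = sigma),
            class = "likelihood_readout")
}

#' @export
print.likelihood_readout <- function(x, ...) {
  cat(sprintf("Likelihood readout: %d simple units, lags %d..%d px\n",
              length(x$bank), min(x$lags), max(x$lags)))
  invisible(x)
}

#' Log-likelihood of disparity from observed simple-unit rates
#'
#' `log L(d) = sum_i r_i (W_L x W_R)_i[d]` -- a biologically plausible
#' weighted sum of the population's firing rates.
#'
#' @param readout A [blm_readout()].
#' @param responses Numeric vector of firing rates, aligned with the bank.
#' @return An object of class `likelihood_curve`: `lags`, `loglik`,
#'   `argmax` (disparity of the maximum).
#' @export
blm_loglik <- function(readout, responses) {
  stopifnot(inherits(readout, "likelihood_readout"))
  if (length(responses) != nrow(readout$weights))
    stop("responses must align with the simple-unit bank")
  ll <- as.vector(crossprod(readout$weights, responses))
  structure(list(lags = readout$lags, loglik = ll,
                 argmax = readout$lags[which.max(ll)]),
            class = "likelihood_curve")
}

#' @export
print.likelihood_curve <- function(x, ...) {
  cat(sprintf("Likelihood curve over %d lags; argmax at %g px\n",
              length(x$lags), x$argmax))
  invisible(x)
}

# internal: build the 3x3 position-by-phase Gabor bank used by the printed
# instantiation; offsets are split symmetrically between the eyes
blm_bank <- function(freq, sigma, dx0, dphi, shape) {
  combos <- expand.grid(dx0 = dx0, dphi = dphi)
  lapply(seq_len(nrow(combos)), function(i) {
    base <- gabor_params(sigma = sigma, freq = freq,
                         x0 = -combos$dx0[i] / 2,
                         phase = wrap_phase(-combos$dphi[i] / 2),
                         theta = pi / 2)
    make_binocular_gabor(base, dx0 = combos$dx0[i], dphi = combos$dphi[i],
                         shape = shape)
  })
}

# internal: disparity tuning of a bank of convolutionally applied simple
# units ("simple unit maps": the response is the nonlinearity applied at
# every valid position, summed over space). Returns, for each nonlinearity
# in `nls`, an array (trials x disparities x units).
bank_tuning <- function(bank, nls, disparities, trials, image_size,
                        density = 0.5, dot_size = 1,
                        correlation = c("correlated", "anticorrelated"),
                        seed = NULL, batch = 50) {
  correlation <- match.arg(correlation)
  kh <- nrow(bank[[1]]$wl); kw <- ncol(bank[[1]]$wl)
  if (image_size < kh) stop("image_size must be at least the RF size")
  W <- vapply(bank, function(u) c(u$wl, u$wr), numeric(kh * kw * 2))
  biases <- vapply(bank, function(u) u$bias, numeric(1))
  m <- max(abs(disparities))
  h <- image_size; w <- image_size
  anti <- correlation == "anticorrelated"
  out <- lapply(nls, function(nl)
    array(NA_real_, c(trials, length(disparities), length(bank))))
  P <- (h - kh + 1) * (w - kw + 1)
  with_seed_if(seed, {
    for (k in seq_along(disparities)) {
      d <- disparities[k]
      done <- 0
      while (done < trials) {
        nb <- min(batch, trials - done)
        L <- array(NA_real_, c(h, w, nb)); R <- array(NA_real_, c(h, w, nb))
        for (t in seq_len(nb)) {
          base <- paint_dot_field(h, w + 2 * m, dot_size, density, "mixed", 0)
          L[, , t] <- base[, (m + 1):(m + w)]
          R[, , t] <- base[, (m + 1 - d):(m + w - d)] * (if (anti) -1 else 1)
        }
        drive <- conv_forward(L, R, W, biases)
        for (j in seq_along(nls)) {
          resp <- apply_nonlinearity(drive, nls[[j]])
          # sum over the P map positions of each trial
          sums <- rowsum(resp, rep(seq_len(nb), each = P))
          out[[j]][done + seq_len(nb), k, ] <- sums
        }
        done <- done + nb
      }
    }
  })
  out
}

# internal: complex-unit spatial-frequency tuning via disparity-matched
# gratings; returns the FWHM bandwidth in octaves
complex_sf_bandwidth <- function(bank, weights, nl, disparity, base_freq,
                                 image_size, n_octaves = 2, n_freq = 81,
                                 n_phase = 16) {
  kh <- nrow(bank[[1]]$wl)
  W <- vapply(bank, function(u) c(u$wl, u$wr), numeric(2 * kh^2))
  freqs <- base_freq * 2^seq(-n_octaves, n_octaves, length.out = n_freq)
  x <- matrix(pixel_grid(image_size), image_size, image_size, byrow = TRUE)
  P <- (image_size - kh + 1)^2
  resp <- vapply(freqs, function(f) {
    acc <- 0
    for (ps in seq(0, 2 * pi, length.out = n_phase + 1)[seq_len(n_phase)]) {
      L <- array(cos(2 * pi * f * x + ps), c(image_size, image_size, 1))
      R <- array(cos(2 * pi * f * (x - disparity) + ps),
                 c(image_size, image_size, 1))
      r <- colSums(apply_nonlinearity(conv_forward(L, R, W, numeric(ncol(W))),
                                      nl))
      acc <- acc + sum(r * weights)
    }
    acc / n_phase
  }, numeric(1))
  spectrum_fwhm_octaves(freqs, resp, floor_level = 0)
}

#' The printed nine-unit instantiation of the binocular likelihood model
#'
#' Builds the 3x3 position-by-phase bank of Gabor simple units
#' (f = 0.0625 cyc/px, bandwidth 1.5 octaves hence sigma = 6.27 px;
#' position disparities \{-3, 0, 3\} px; phase disparities
#' \{-pi, -pi/3, pi/3\} rad), reads them out with two complex units (one
#' preferring near, one far) whose weights are the units'
#' cross-correlograms evaluated at the preferred lags, and measures
#' disparity tuning to correlated and anticorrelated random-dot stereograms
#' (mixed polarity, 50% density, 1-px dots). Tuning curves are fitted with
#' Gabors (with a DC offset) to obtain the aRDS/cRDS amplitude ratio, and
#' the complex unit's spatial-frequency bandwidth is measured with
#' disparity-matched gratings.
#'
#' @param freq Simple-unit spatial frequency, cycles/pixel.
#' @param bandwidth Simple-unit spatial-frequency bandwidth, octaves.
#' @param dx0,dphi Position (px) and phase (rad) disparity sets.
#' @param nl Simple-unit output [nonlinearity()] for the tuning curves
#'   (linear rectification by default, as in the network the model
#'   summarizes).
#' @param disparities Stimulus disparity grid, pixels.
#' @param trials Trials per disparity.
#' @param image_size Stimulus side, pixels (receptive fields are applied
#'   convolutionally and summed over space).
#' @param pref_disparities Preferred lags (px) of the near and far complex
#'   units.
#' @param measure_bandwidth Also measure the complex unit's
#'   spatial-frequency bandwidth (uses the squaring regime of the analytic
#'   derivation; see the methods vignette).
#' @param seed RNG seed for the stimulus ensembles.
#' @return A list: `bank`, `readout` (2 x units weight matrix),
#'   `tuning` (per condition: complex-unit [tuning_curve()]s),
#'   `fits`, `amplitude_ratio` (mean over complex units),
#'   `bandwidth_complex` (octaves), `bandwidth_simple`, `params`.
#' @export
blm_instantiate_9 <- function(freq = 0.0625, bandwidth = 1.5,
                              dx0 = c(-3, 0, 3),
                              dphi = c(-pi, -pi / 3, pi / 3),
                              nl = nonlinearity("relu"),
                              disparities = -20:20, trials = 100,
                              image_size = 44,
                              pref_disparities = c(near = -3, far = 3),
                              measure_bandwidth = TRUE, seed = 1) {
  sigma <- sigma_from_bandwidth(freq, bandwidth)
  shape <- rep(2 * ceiling(3 * sigma) + 1, 2)
  bank <- blm_bank(freq, sigma, dx0, dphi, shape)
  pref <- round(pref_disparities)
  weights <- t(vapply(bank, rf_cross_correlogram, numeric(length(pref)),
                      lags = pref))                    # units x 2
  tuning <- lapply(c(correlated = "correlated",
                     anticorrelated = "anticorrelated"), function(cond) {
    simple <- bank_tuning(bank, list(nl), disparities, trials, image_size,
                          correlation = cond, seed = seed)[[1]]
    lapply(seq_along(pref), function(j) {
      trials_mat <- matrix(0, dim(simple)[1], dim(simple)[2])
      for (i in seq_along(bank))
        trials_mat <- trials_mat + simple[, , i] * weights[i, j]
      tuning_curve(disparities, trials_mat,
                   ensemble = list(correlation = cond,
                                   unit = names(pref)[j]))
    })
  })
  fits <- lapply(seq_along(pref), function(j) {
    fc <- fit_gabor_1d(tuning$correlated[[j]]$mean, disparities, offset = TRUE)
    fa <- fit_gabor_1d(tuning$anticorrelated[[j]]$mean, disparities,
                       offset = TRUE)
    list(correlated = fc, anticorrelated = fa,
         ratio = fa$params$amplitude / fc$params$amplitude)
  })
  names(fits) <- names(pref)
  ratio <- mean(vapply(fits, `[[`, numeric(1), "ratio"))
  bw <- if (measure_bandwidth) {
    complex_sf_bandwidth(bank, weights[, which.max(pref)],
                         nl = nonlinearity("squaring"),
                         disparity = pref[which.max(pref)],
                         base_freq = freq, image_size = image_size)
  } else NA_real_
  list(bank = bank, readout = t(weights), tuning = tuning, fits = fits,
       amplitude_ratio = ratio, bandwidth_complex = bw,
       bandwidth_simple = bandwidth,
       params = list(freq = freq, sigma = sigma, dx0 = dx0, dphi = dphi,
                     pref_disparities = pref, trials = trials,
                     image_size = image_size, seed = seed))
}

#' Effect of the simple-cell output exponent on aRDS attenuation
#'
#' Reruns the nine-unit instantiation with the simple-cell nonlinearity set
#' to a rectified power `max(x, 0)^p` for each exponent and returns the
#' aRDS/cRDS amplitude ratio. Compressive exponents (p < 1) deepen the
#' attenuation; expansive exponents reduce it, so the ratio is
#' non-decreasing in the exponent.
#'
#' @param exponents Positive exponents to evaluate.
#' @param ... Passed to [blm_instantiate_9()] (bandwidth measurement is
#'   skipped).
#' @param disparities,trials,image_size,seed As [blm_instantiate_9()].
#' @return Data frame with `exponent` and `amplitude_ratio`.
#' @export
nonlinearity_effect <- function(exponents = c(0.5, 1, 1.5, 2),
                                disparities = -20:20, trials = 100,
                                image_size = 44, seed = 1, ...) {
  if (any(exponents <= 0)) stop("exponents must be > 0")
  args <- list(...)
  freq <- if (is.null(args$freq)) 0.0625 else args$freq
  bandwidth <- if (is.null(args$bandwidth)) 1.5 else args$bandwidth
  dx0 <- if (is.null(args$dx0)) c(-3, 0, 3) else args$dx0
  dphi <- if (is.null(args$dphi)) c(-pi, -pi / 3, pi / 3) else args$dphi
  pref <- if (is.null(args$pref_disparities)) c(near = -3, far = 3) else
    args$pref_disparities
  sigma <- sigma_from_bandwidth(freq, bandwidth)
  shape <- rep(2 * ceiling(3 * sigma) + 1, 2)
  bank <- blm_bank(freq, sigma, dx0, dphi, shape)
  weights <- t(vapply(bank, rf_cross_correlogram, numeric(length(pref)),
                      lags = round(pref)))
  nls <- lapply(exponents, function(p) nonlinearity("power", exponent = p))
  ratios <- vapply(seq_along(exponents), function(x) NA_real_, numeric(1))
  simple <- lapply(c("correlated", "anticorrelated"), function(cond)
    bank_tuning(bank, nls, disparities, trials, image_size,
                correlation = cond, seed = seed))
  names(simple) <- c("correlated", "anticorrelated")
  for (e in seq_along(exponents)) {
    rr <- vapply(seq_len(ncol(weights)), function(j) {
      cmplx <- function(cond) {
        s <- simple[[cond]][[e]]
        m <- matrix(0, dim(s)[1], dim(s)[2])
        for (i in seq_along(bank)) m <- m + s[, , i] * weights[i, j]
        colMeans(m)
      }
      fc <- fit_gabor_1d(cmplx("correlated"), disparities, offset = TRUE)
      fa <- fit_gabor_1d(cmplx("anticorrelated"), disparities, offset = TRUE)
      fa$params$amplitude / fc$params$amplitude
    }, numeric(1))
    ratios[e] <- mean(rr)
  }
  data.frame(exponent = exponents, amplitude_ratio = ratios)
}
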