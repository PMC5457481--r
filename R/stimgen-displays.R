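#' Wallpaper (periodic stripe) stereogram
#'
#' A central square region of vertical stripes, identical in both eyes, so
#' that global matches are valid at every multiple of the stripe period
#' (ambiguous depth). The surrounding background luminance is a free
#' parameter: varying it biases which match is perceived, and the biased
#' variants differ only in that luminance.
#'
#' @param period Stripe period, pixels (>= 2).
#' @param size Image size, pixels.
#' @param bg_luminance Background luminance in `[-1, 1]`.
#' @param stripe_high,stripe_low Stripe luminances.
#' @param duty Fraction of the period at `stripe_high`.
#' @param region_frac Side of the central stripe region as a fraction of the
#'   image.
#' @return A [stereo_pair()].
#' @export
make_wallpaper <- function(period = 8, size = 160, bg_luminance = 0,
                           stripe_high = 1, stripe_low = -1, duty = 0.5,
                           region_frac = 0.5) {
  if (period < 2) stop("period must be >= 2 px")
  if (length(size) == 1) size <- c(size, size)
  nr <- size[1]; nc <- size[2]
  img <- matrix(bg_luminance, nr, nc)
  half_h <- round(region_frac * nr / 2); half_w <- round(region_frac * nc / 2)
  rr <- (round(nr / 2) - half_h):(round(nr / 2) + half_h - 1)
  cc <- (round(nc / 2) - half_w):(round(nc / 2) + half_w - 1)
  phase <- (cc - cc[1]) %% period
  stripe <- ifelse(phase < duty * period, stripe_high, stripe_low)
  img[rr, cc] <- matrix(stripe, length(rr), length(cc), byrow = TRUE)
  stereo_pair(img, img, period = period, bg_luminance = bg_luminance,
              region_rows = range(rr), region_cols = range(cc))
}

#' da Vinci (half-occlusion) stereogram
#'
#' A central target at zero disparity flanked at its vertical edges by
#' monocular strips: the left flank is visible only in the left eye and the
#' right flank only in the right eye, as produced by occlusion geometry when
#' the target is nearer than the background. The occlusion mask marks the
#' monocular flank pixels. Alternative luminance configurations are
#' supported through the luminance arguments.
#'
#' @param size Image size, pixels.
#' @param target_width,target_height Target size, pixels.
#' @param flank_width Monocular flank width, pixels (>= 1).
#' @param target_luminance,flank_luminance,bg_luminance Luminances in
#'   `[-1, 1]` (dark flanks by default).
#' @return A [stereo_pair()] with the monocular mask.
#' @export
make_davinci <- function(size = 160, target_width = 40, target_height = 80,
                         flank_width = 8, target_luminance = 1,
                         flank_luminance = -1, bg_luminance = 0) {
  if (flank_width < 1) stop("flank_width must be >= 1 px")
  if (length(size) == 1) size <- c(size, size)
  nr <- size[1]; nc <- size[2]
  left <- matrix(bg_luminance, nr, nc)
  rr <- (round(nr / 2) - round(target_height / 2)):
        (round(nr / 2) + round(target_height / 2) - 1)
  cc <- (round(nc / 2) - round(target_width / 2)):
        (round(nc / 2) + round(target_width / 2) - 1)
  left[rr, cc] <- target_luminance
  right <- left
  mask <- matrix(FALSE, nr, nc)
  lf <- (min(cc) - flank_width):(min(cc) - 1)      # left-edge flank
  rf <- (max(cc) + 1):(max(cc) + flank_width)      # right-edge flank
  left[rr, lf] <- flank_luminance
  right[rr, rf] <- flank_luminance
  mask[rr, c(lf, rf)] <- TRUE
  stereo_pair(left, right, mask = mask,
              target_rows = range(rr), target_cols = range(cc),
              flank_cols = list(left_eye = range(lf), right_eye = range(rf)))
}
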