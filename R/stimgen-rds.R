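#' Random-dot stereogram configuration
#'
#' @param size Image size in pixels, `c(rows, cols)` or a scalar.
#' @param dot_size Dot side length, pixels (>= 1).
#' @param density Fraction of pixels covered by dots, in (0, 1].
#' @param polarity `"mixed"` (equal numbers of bright and dark dots),
#'   `"bright"` or `"dark"`.
#' @param disparity Uniform disparity, pixels (positive = far).
#' @param correlation `"correlated"` or `"anticorrelated"` (contrast inverted
#'   in one eye; see `anticorrelate_eye`).
#' @param background Background intensity (mid-gray 0 by default; bright,
#'   dark and mid-gray pixels are +1, -1 and 0).
#' @param anticorrelate_eye Which eye's contrast to invert, `"right"`
#'   (default) or `"left"`.
#' @param seed Optional RNG seed.
#' @return A list of class `rds_config`.
#' @export
rds_config <- function(size = c(100, 100), dot_size = 1, density = 0.5,
                       polarity = c("mixed", "bright", "dark"),
                       disparity = 0,
                       correlation = c("correlated", "anticorrelated"),
                       background = 0, anticorrelate_eye = c("right", "left"),
                       seed = NULL) {
  if (length(size) == 1) size <- c(size, size)
  polarity <- match.arg(polarity)
  correlation <- match.arg(correlation)
  anticorrelate_eye <- match.arg(anticorrelate_eye)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (dot_size < 1) stop("dot_size must be >= 1")
  structure(list(size = size, dot_size = dot_size, density = density,
                 polarity = polarity, disparity = disparity,
                 correlation = correlation, background = background,
                 anticorrelate_eye = anticorrelate_eye, seed = seed),
            class = "rds_config")
}

# internal: paint a field of square dots onto a background matrix.
# For dot_size 1 each pixel is independently a dot with probability density;
# for larger dots, dot count is chosen to reach the requested coverage.
paint_dot_field <- function(nr, nc, dot_size, density, polarity, background) {
  img <- matrix(background, nr, nc)
  dot_value <- function(n) switch(polarity,
    mixed = sample(c(-1, 1), n, replace = TRUE),
    bright = rep(1, n),
    dark = rep(-1, n))
  if (dot_size == 1) {
    on <- runif(nr * nc) < density
    img[on] <- dot_value(sum(on))
  } else {
    n_dots <- round(density * nr * nc / dot_size^2)
    r0 <- sample.int(nr - dot_size + 1, n_dots, replace = TRUE)
    c0 <- sample.int(nc - dot_size + 1, n_dots, replace = TRUE)
    val <- dot_value(n_dots)
    for (i in seq_len(n_dots)) {
      img[r0[i]:(r0[i] + dot_size - 1), c0[i]:(c0[i] + dot_size - 1)] <- val[i]
    }
  }
  img
}

#' Generate a random-dot stereogram
#'
#' Dots are placed on a wide base field; the two eyes' images are crops of
#' the base offset horizontally by the disparity, so positive disparities
#' shift right-eye features rightwards. Anticorrelation inverts contrast in
#' the configured eye (background pixels, at mid-gray 0, are unaffected).
#'
#' @param config An [rds_config()].
#' @return A [stereo_pair()] with the imposed disparity recorded in metadata.
#' @export
make_rds <- function(config) {
  stopifnot(inherits(config, "rds_config"))
  with_seed_if(config$seed, {
    nr <- config$size[1]; nc <- config$size[2]
    d <- round(config$disparity)
    m <- abs(d) + config$dot_size
    base <- paint_dot_field(nr, nc + 2 * m, config$dot_size, config$density,
                            config$polarity, config$background)
    left <- base[, (m + 1):(m + nc), drop = FALSE]
    right <- base[, (m + 1 - d):(m + nc - d), drop = FALSE]
    if (config$correlation == "anticorrelated") {
      if (config$anticorrelate_eye == "right") right <- -right else left <- -left
    }
    stereo_pair(left, right, disparity = d, config = config)
  })
}

#' Step-edge stereogram configuration
#'
#' Defaults follow the stimulus used for the polarity psychophysics task:
#' 240 x 240 px, 8-px dots at ~15% density with no dot-dot occlusion, a 2-px
#' disparity step between the two halves, and per-dot Gaussian disparity
#' noise of 8 px (rounded to integer pixels).
#'
#' @param size Image size, pixels.
#' @param dot_size Dot side length, pixels.
#' @param density Approximate fraction of pixels covered.
#' @param step Disparity step between halves, pixels (each half gets
#'   +/- step/2).
#' @param noise_sd Per-dot Gaussian disparity noise SD, pixels.
#' @param polarity `"mixed"`, `"bright"` or `"dark"`.
#' @param near_side Which half is near: `"left"` or `"right"`.
#' @param seed Optional RNG seed.
#' @export
step_edge_config <- function(size = 240, dot_size = 8, density = 0.15,
                             step = 2, noise_sd = 8,
                             polarity = c("mixed", "bright", "dark"),
                             near_side = c("left", "right"), seed = NULL) {
  polarity <- match.arg(polarity)
  near_side <- match.arg(near_side)
  if (length(size) == 1) size <- c(size, size)
  structure(list(size = size, dot_size = dot_size, density = density,
                 step = step, noise_sd = noise_sd, polarity = polarity,
                 near_side = near_side, seed = seed),
            class = "step_edge_config")
}

#' Generate a step-edge random-dot stereogram
#'
#' Dots are placed without mutual overlap (rejection sampling with a bounded
#' retry budget). Each dot's disparity is the step offset of its half
#' (near = negative, far = positive) plus Gaussian noise rounded to integer
#' pixels; the dot is drawn at its base position in the left eye and shifted
#' by its disparity in the right eye.
#'
#' @param config A [step_edge_config()].
#' @return A [stereo_pair()]; metadata records the arrangement and the per-dot
#'   positions and disparities.
#' @export
make_step_edge <- function(config) {
  stopifnot(inherits(config, "step_edge_config"))
  with_seed_if(config$seed, {
    nr <- config$size[1]; nc <- config$size[2]
    ds <- config$dot_size
    n_dots <- round(config$density * nr * nc / ds^2)
    # rejection-sample non-overlapping top-left corners
    rows <- integer(n_dots); cols <- integer(n_dots)
    occupied <- matrix(FALSE, nr, nc)
    placed <- 0; tries <- 0; max_tries <- 200 * n_dots
    margin <- ceiling(abs(config$step) / 2 + 3 * config$noise_sd) + ds
    while (placed < n_dots && tries < max_tries) {
      tries <- tries + 1
      r0 <- sample.int(nr - ds + 1, 1)
      c0 <- sample.int(max(nc - ds + 1 - 2 * margin, 1), 1) + margin
      rr <- r0:(r0 + ds - 1); cc <- c0:(c0 + ds - 1)
      if (!any(occupied[rr, cc])) {
        occupied[rr, cc] <- TRUE
        placed <- placed + 1
        rows[placed] <- r0; cols[placed] <- c0
      }
    }
    if (placed < n_dots)
      stop("could not place requested dot density without overlap")
    val <- switch(config$polarity,
      mixed = sample(rep(c(-1, 1), length.out = n_dots)),
      bright = rep(1, n_dots),
      dark = rep(-1, n_dots))
    centers_x <- cols + (ds - 1) / 2
    near_left <- config$near_side == "left"
    on_left_half <- centers_x <= nc / 2
    half_sign <- ifelse(xor(on_left_half, near_left), 1, -1)  # +1 = far half
    disp <- half_sign * config$step / 2 + rnorm(n_dots, 0, config$noise_sd)
    disp <- round(disp)
    dots <- data.frame(row = rows, col = cols, value = val, disparity = disp)
    paint_step_pair(dots, nr, nc, ds, config)
  })
}

# internal: render a step-edge pair from an existing dot layout; used to
# re-render one geometry at several polarities (paired comparisons)
paint_step_pair <- function(dots, nr, nc, ds, config) {
  left <- matrix(0, nr, nc); right <- matrix(0, nr, nc)
  for (i in seq_len(nrow(dots))) {
    rr <- dots$row[i]:(dots$row[i] + ds - 1)
    cc <- dots$col[i]:(dots$col[i] + ds - 1)
    left[rr, cc] <- dots$value[i]
    cs <- cc + dots$disparity[i]
    ok <- cs >= 1 & cs <= nc
    right[rr, cs[ok]] <- dots$value[i]
  }
  stereo_pair(left, right,
              near_side = config$near_side, config = config, dots = dots)
}

# internal: change the polarity of an existing layout
repolarize_dots <- function(dots, polarity) {
  dots$value <- switch(polarity,
    mixed = dots$value,
    bright = abs(dots$value),
    dark = -abs(dots$value))
  dots
}

#' Luminance controls for polarity comparisons
#'
#' Transformations applied per image to rule out low-level covariates when
#' comparing mixed- versus single-polarity stereograms:
#' \describe{
#'   \item{`dc-removed`}{subtract each image's mean luminance.}
#'   \item{`range-matched`}{affine rescale so intensities span `[-1, 1]`
#'     (peak-to-trough range 2).}
#'   \item{`range-matched-after-dc`}{remove the mean, then scale so the
#'     peak-to-trough range equals `reference_range` (the mixed-polarity
#'     range after DC removal); zero mean is preserved, so values may exceed
#'     `[-1, 1]` and the range check is relaxed.}
#' }
#'
#' @param pair A [stereo_pair()].
#' @param mode One of the modes above.
#' @param reference_range Target peak-to-trough range for
#'   `range-matched-after-dc`.
#' @return A transformed [stereo_pair()].
#' @export
polarity_controls <- function(pair,
                              mode = c("dc-removed", "range-matched",
                                       "range-matched-after-dc"),
                              reference_range = 2) {
  stopifnot(inherits(pair, "stereo_pair"))
  mode <- match.arg(mode)
  tf <- switch(mode,
    "dc-removed" = function(m) m - mean(m),
    "range-matched" = function(m) {
      r <- range(m)
      if (diff(r) == 0) return(m * 0)
      2 * (m - r[1]) / diff(r) - 1
    },
    "range-matched-after-dc" = function(m) {
      m <- m - mean(m)
      r <- diff(range(m))
      if (r == 0) return(m)
      m * (reference_range / r)
    })
  stereo_pair(tf(pair$left), tf(pair$right), disparity = pair$disparity,
              mask = pair$mask, check_range = FALSE,
              control = mode, parent_meta = pair$meta)
}
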