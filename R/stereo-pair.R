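#' Stereo image pair
#'
#' Two co-registered gray-scale images in `[-1, 1]`, optionally with a
#' ground-truth disparity map (pixels) and an occlusion/interpolation mask.
#'
#' @param left,right Numeric matrices of identical shape, values in `[-1, 1]`.
#' @param disparity Optional disparity map (same shape), pixels, positive =
#'   far (see `?binodepth-conventions`).
#' @param mask Optional logical matrix marking interpolated (disoccluded) or
#'   monocular pixels.
#' @param check_range If `FALSE`, skip the `[-1, 1]` intensity check (used by
#'   luminance-control transformations that deliberately rescale).
#' @param ... Extra metadata stored alongside the images.
#' @return An object of class `stereo_pair`.
#' @export
stereo_pair <- function(left, right, disparity = NULL, mask = NULL,
                        check_range = TRUE, ...) {
  left <- as.matrix(left); right <- as.matrix(right)
  if (!identical(dim(left), dim(right))) stop("left/right shapes must match")
  if (check_range) {
    tol <- 1e-8
    if (max(abs(left), abs(right)) > 1 + tol)
      stop("intensities must lie within [-1, 1]")
  }
  if (!is.null(disparity) && length(disparity) == 1)
    disparity <- matrix(disparity, nrow(left), ncol(left))
  if (!is.null(disparity) && !identical(dim(disparity), dim(left)))
    stop("disparity map shape must match the images")
  if (!is.null(mask) && !identical(dim(mask), dim(left)))
    stop("mask shape must match the images")
  structure(list(left = left, right = right, disparity = disparity,
                 mask = mask, meta = list(...)),
            class = "stereo_pair")
}

#' @export
print.stereo_pair <- function(x, ...) {
  cat(sprintf("Stereo pair: %d x %d px, intensities [%.3f, %.3f]%s%s\n",
              nrow(x$left), ncol(x$left),
              min(x$left, x$right), max(x$left, x$right),
              if (!is.null(x$disparity)) ", with disparity map" else "",
              if (!is.null(x$mask)) ", with mask" else ""))
  invisible(x)
}

#' Export a stereo pair as PNG images
#'
#' Writes per-eye images, a side-by-side arrangement for cross-eyed fusion,
#' or a red/green anaglyph. Requires the `png` package.
#'
#' @param pair A [stereo_pair()].
#' @param prefix Output path prefix (files get `_L.png`/`_R.png`, `_sbs.png`
#'   or `_anaglyph.png` suffixes).
#' @param mode One of `"eyes"`, `"sbs"`, `"anaglyph"`.
#' @return The file path(s), invisibly.
#' @export
write_stereo_png <- function(pair, prefix, mode = c("eyes", "sbs", "anaglyph")) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  mode <- match.arg(mode)
  to01 <- function(m) pmin(pmax((m + 1) / 2, 0), 1)
  paths <- switch(mode,
    eyes = {
      pl <- paste0(prefix, "_L.png"); pr <- paste0(prefix, "_R.png")
      png::writePNG(to01(pair$left), pl)
      png::writePNG(to01(pair$right), pr)
      c(pl, pr)
    },
    sbs = {
      p <- paste0(prefix, "_sbs.png")
      png::writePNG(cbind(to01(pair$left), to01(pair$right)), p)
      p
    },
    anaglyph = {
      p <- paste0(prefix, "_anaglyph.png")
      img <- array(0, c(dim(pair$left), 3))
      img[, , 1] <- to01(pair$left)
      img[, , 2] <- to01(pair$right)
      png::writePNG(img, p)
      p
    })
  invisible(paths)
}
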