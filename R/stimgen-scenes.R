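#' Synthetic naturalistic scene specification
#'
#' Parameters of the synthetic stand-in for photographic stereo material: a
#' gray-scale texture with a power-law (1/f-like) spatial amplitude spectrum
#' and a piecewise-smooth depth map composed of a configurable number of
#' fronto-parallel surfaces.
#'
#' @param size Scene size in pixels (square).
#' @param spectral_slope Log-log slope of the texture amplitude spectrum
#'   (-1 gives natural-image-like 1/f statistics).
#' @param contrast Texture RMS contrast on the `[0, 1]` gray-level scale.
#' @param n_surfaces Number of depth surfaces (background + n-1 occluders).
#' @param depth_range Range the surface depths are drawn from; negative =
#'   near, positive = far.
#' @param max_shift Maximum rendered pixel shift (pixels).
#' @param seed Optional RNG seed.
#' @export
scene_spec <- function(size = 160, spectral_slope = -1, contrast = 0.15,
                       n_surfaces = 3, depth_range = c(-1, 1),
                       max_shift = 10, seed = NULL) {
  if (length(size) == 1) size <- c(size, size)
  stopifnot(n_surfaces >= 1, max_shift >= 0)
  structure(list(size = size, spectral_slope = spectral_slope,
                 contrast = contrast, n_surfaces = n_surfaces,
                 depth_range = depth_range, max_shift = max_shift,
                 seed = seed),
            class = "scene_spec")
}

#' Generate a synthetic textured scene with a depth map
#'
#' The texture is white noise filtered in the Fourier domain with a radial
#' power-law gain, standardized to the requested contrast around mid-gray on
#' the `[0, 1]` scale. The depth map is a background plane overlaid with
#' randomly placed elliptical surfaces, each at a constant depth drawn from
#' `depth_range` (nearer surfaces painted last), giving a piecewise-smooth
#' map. Deterministic under `seed`.
#'
#' @param spec A [scene_spec()].
#' @return A list with `texture` (matrix in `[0, 1]`) and `depth` (matrix).
#' @export
synth_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed_if(spec$seed, {
    nr <- spec$size[1]; nc <- spec$size[2]
    # power-law texture
    wn <- matrix(rnorm(nr * nc), nr, nc)
    fr <- c(seq(0, floor(nr / 2)), seq(-(ceiling(nr / 2) - 1), -1)) / nr
    fc <- c(seq(0, floor(nc / 2)), seq(-(ceiling(nc / 2) - 1), -1)) / nc
    rad <- sqrt(outer(fr^2, fc^2, "+"))
    gain <- ifelse(rad > 0, rad^spec$spectral_slope, 0)
    tex <- Re(fft(fft(wn) * gain, inverse = TRUE)) / (nr * nc)
    tex <- (tex - mean(tex)) / sd(tex) * spec$contrast + 0.5
    tex <- pmin(pmax(tex, 0), 1)
    # piecewise-constant depth map from layered ellipses
    depths <- runif(spec$n_surfaces, spec$depth_range[1], spec$depth_range[2])
    depth <- matrix(depths[1], nr, nc)
    if (spec$n_surfaces > 1) {
      # paint far-to-near so nearer surfaces occlude
      ord <- order(depths[-1], decreasing = TRUE)
      yy <- matrix(seq_len(nr), nr, nc)
      xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      for (i in ord) {
        cy <- runif(1, 0.2 * nr, 0.8 * nr); cx <- runif(1, 0.2 * nc, 0.8 * nc)
        ay <- runif(1, 0.15 * nr, 0.45 * nr); ax <- runif(1, 0.15 * nc, 0.45 * nc)
        inside <- ((yy - cy) / ay)^2 + ((xx - cx) / ax)^2 <= 1
        depth[inside] <- depths[i + 1]
      }
    }
    list(texture = tex, depth = depth, spec = spec)
  })
}

#' Render a stereo pair from a texture and a depth map
#'
#' The left image is the texture; the right image is produced by shifting
#' each pixel horizontally by a disparity proportional to its depth, scaled
#' so the scene's maximum absolute depth maps to `max_shift` pixels
#' (positive depth = far = rightward shift in the right eye). Where several
#' sources land on the same target pixel the nearest surface wins;
#' disoccluded pixels are filled by linear interpolation along the row and
#' flagged in the returned mask.
#'
#' @param texture Matrix in `[0, 1]` (gray levels).
#' @param depth Co-registered depth map; must be finite.
#' @param max_shift Maximum pixel shift (default 10).
#' @return A [stereo_pair()] with intensities scaled to `[-1, 1]`, the
#'   rendered integer disparity map, and the interpolation mask.
#' @export
render_stereo_from_depth <- function(texture, depth, max_shift = 10) {
  texture <- as.matrix(texture); depth <- as.matrix(depth)
  if (!all(is.finite(depth))) stop("depth map must be finite")
  if (!identical(dim(texture), dim(depth)))
    stop("texture and depth must be co-registered")
  nr <- nrow(texture); nc <- ncol(texture)
  mx <- max(abs(depth))
  disp <- if (mx > 0) round(depth / mx * max_shift) else depth * 0
  right <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    d <- disp[r, ]
    # nearest (most negative depth) written last so it wins collisions
    ord <- order(depth[r, ], decreasing = TRUE)
    xt <- seq_len(nc) + d
    keep <- xt >= 1 & xt <= nc
    src <- ord[keep[ord]]
    right[r, xt[src]] <- texture[r, src]
  }
  mask <- is.na(right)
  if (any(mask)) {
    for (r in seq_len(nr)) {
      row <- right[r, ]
      if (anyNA(row)) {
        known <- which(!is.na(row))
        if (length(known) >= 2) {
          row <- approx(known, row[known], xout = seq_len(nc), rule = 2)$y
        } else if (length(known) == 1) {
          row[] <- row[known]
        } else row[] <- mean(texture[r, ])
        right[r, ] <- row
      }
    }
  }
  stereo_pair(2 * texture - 1, 2 * right - 1, disparity = disp, mask = mask,
              max_shift = max_shift)
}

#' Extract labeled training patches from rendered stereo pairs
#'
#' Cuts each pair into `patch` x `patch` windows on a regular grid, discards
#' patches with low texture variance (gray-level SD below `sd_threshold` on
#' the 0-255 scale, evaluated in either eye), patches with more than
#' `max_interp` interpolated pixels, and patches without a clean single-depth
#' label (mean absolute disparity below `min_abs_disp` or disparity SD above
#' `max_disp_sd`). Survivors are labeled near/far by the sign of their mean
#' ground-truth disparity, class-balanced, shuffled, and split into disjoint
#' train/validation/test sets.
#'
#' @param pairs List of [stereo_pair()] objects carrying disparity maps and
#'   interpolation masks (from [render_stereo_from_depth()]).
#' @param patch Patch side, pixels.
#' @param stride Grid stride, pixels.
#' @param sd_threshold Gray-level SD threshold (0-255 scale).
#' @param max_interp Maximum tolerated fraction of interpolated pixels.
#' @param split Train/validation/test proportions (must sum to 1).
#' @param min_abs_disp,max_abs_disp Bounds on |mean disparity| for a
#'   labeled patch, pixels.
#' @param max_disp_sd Maximum within-patch disparity SD, pixels.
#' @param balance Balance the near/far classes by downsampling.
#' @param seed Optional RNG seed for the shuffle/split.
#' @return A list with elements `train`, `val`, `test`, each a `patch_set`:
#'   list of arrays `left`, `right` (patch x patch x n), factor `label`
#'   (levels near, far) and numeric `disparity` (mean patch disparity).
#' @export
extract_patches <- function(pairs, patch = 30, stride = 15,
                            sd_threshold = 20, max_interp = 0.05,
                            split = c(0.70, 0.15, 0.15),
                            min_abs_disp = 1, max_abs_disp = Inf,
                            max_disp_sd = 0.75,
                            balance = TRUE, seed = NULL) {
  stopifnot(abs(sum(split) - 1) < 1e-9, length(split) == 3)
  sd_thr <- sd_threshold / 255 * 2   # [-1, 1] intensity units
  L <- list(); R <- list(); lab <- c(); dsp <- c()
  for (pair in pairs) {
    if (is.null(pair$mask) || is.null(pair$disparity))
      stop("pairs must carry interpolation masks and disparity maps")
    nr <- nrow(pair$left); nc <- ncol(pair$left)
    r0s <- seq(1, nr - patch + 1, by = stride)
    c0s <- seq(1, nc - patch + 1, by = stride)
    for (r0 in r0s) for (c0 in c0s) {
      rr <- r0:(r0 + patch - 1); cc <- c0:(c0 + patch - 1)
      pl <- pair$left[rr, cc]; pr <- pair$right[rr, cc]
      if (min(sd(pl), sd(pr)) < sd_thr) next
      if (mean(pair$mask[rr, cc]) > max_interp) next
      d <- pair$disparity[rr, cc]
      md <- mean(d)
      if (abs(md) < min_abs_disp || abs(md) > max_abs_disp ||
          sd(d) > max_disp_sd) next
      L[[length(L) + 1]] <- pl; R[[length(R) + 1]] <- pr
      lab <- c(lab, if (md < 0) "near" else "far")
      dsp <- c(dsp, md)
    }
  }
  n <- length(L)
  if (n < 6) stop("too few surviving patches to split")
  lab <- factor(lab, levels = c("near", "far"))
  with_seed_if(seed, {
    keep <- seq_len(n)
    if (balance) {
      k <- min(table(lab))
      keep <- c(sample(which(lab == "near"), k), sample(which(lab == "far"), k))
    }
    keep <- sample(keep)
    n <- length(keep)
    n_train <- floor(split[1] * n); n_val <- floor(split[2] * n)
    if (n_train < 1 || n_val < 1 || n_train + n_val >= n)
      stop("too few surviving patches to split")
    idx <- list(train = keep[seq_len(n_train)],
                val = keep[n_train + seq_len(n_val)],
                test = keep[(n_train + n_val + 1):n])
    make_set <- function(i) {
      structure(list(
        left = array(unlist(L[i]), c(patch, patch, length(i))),
        right = array(unlist(R[i]), c(patch, patch, length(i))),
        label = lab[i], disparity = dsp[i]), class = "patch_set")
    }
    lapply(idx, make_set)
  })
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("Patch set: %d patches of %d x %d px (%s)\n",
              dim(x$left)[3], dim(x$left)[1], dim(x$left)[2],
              paste(sprintf("%s=%d", levels(x$label), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}

#' Generate a labeled naturalistic patch corpus
#'
#' Convenience pipeline: synthesize `n_scenes` scenes, render each at one or
#' more disparity scales (mirroring a series of refocusings of the same
#' scene, which multiplies the stereo pairs available per scene and
#' populates the disparity classes the network is trained on), and extract
#' labeled patch sets. This is the training corpus for the binocular
#' network.
#'
#' @param n_scenes Number of synthetic scenes.
#' @param spec A [scene_spec()] template (its seed is ignored; per-scene
#'   seeds derive from `seed`).
#' @param max_shifts Maximum pixel shift(s) to render each scene at.
#' @param seed Master seed.
#' @param ... Passed to [extract_patches()].
#' @return As [extract_patches()].
#' @export
make_patch_corpus <- function(n_scenes = 50, spec = scene_spec(),
                              max_shifts = spec$max_shift, seed = 1, ...) {
  scene_seeds <- with_seed_if(seed, sample.int(2^31 - 2, n_scenes))
  pairs <- list()
  for (s in scene_seeds) {
    spec$seed <- s
    sc <- synth_scene(spec)
    for (ms in max_shifts) {
      pairs[[length(pairs) + 1]] <-
        render_stereo_from_depth(sc$texture, sc$depth, ms)
    }
  }
  extract_patches(pairs, seed = seed, ...)
}
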