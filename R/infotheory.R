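#' Joint response distribution of a small population of simple units
#'
#' Responds a bank of up to 5 binocular simple units to broadband stereo
#' noise (i.i.d. uniform intensities in `[-1, 1]`, right eye a horizontally
#' shifted copy of the left) at each disparity, quantizes the rates into
#' equal-width bins over each unit's observed range, and tabulates the joint
#' response histogram conditioned on disparity. The joint histogram has
#' `bins^N` cells, which is why the population size is capped: memory grows
#' exponentially with N.
#'
#' @param units List of [binocular_rf()] objects (1 to 5, identical shapes).
#' @param nl A [nonlinearity()] (rectified squaring by default, the standard
#'   energy-model output stage).
#' @param disparities Integer disparity grid, pixels.
#' @param n_stim Total number of stimuli (split evenly across disparities).
#' @param bins Response bins per unit.
#' @param seed Optional RNG seed.
#' @return An object of class `response_distribution` with the conditional
#'   probabilities `cond` (`bins^N` x n-disparities), `marginal`, uniform
#'   `prior`, `disparities`, `bin_edges`, and bookkeeping fields.
#' @export
response_distribution <- function(units, nl = nonlinearity("rectified-squaring"),
                                  disparities = -20:20, n_stim = 100000,
                                  bins = 10, seed = NULL) {
  if (inherits(units, "binocular_rf")) units <- list(units)
  n_units <- length(units)
  if (n_units > 5) {
    bytes <- as.numeric(bins)^n_units * length(disparities) * 8
    stop(sprintf(paste0("joint histograms are limited to 5 units: %d units with ",
                        "%d bins would need ~%.1f GB"),
                 n_units, bins, bytes / 1e9))
  }
  shapes <- vapply(units, function(u) dim(u$wl), integer(2))
  if (any(shapes != shapes[, 1])) stop("all units must share one RF shape")
  resp <- unit_responses(units, nl, disparities, n_stim, seed)
  quantize_responses(resp$responses, resp$disparity_index, disparities, bins)
}

# internal: responses (n_stim x n_units) of a unit bank to the uniform-noise
# ensemble; all units see the same stimuli
unit_responses <- function(units, nl, disparities, n_stim, seed = NULL) {
  h <- dim(units[[1]]$wl)[1]; w <- dim(units[[1]]$wl)[2]
  m <- max(abs(disparities))
  W <- vapply(units, function(u) c(u$wl, u$wr), numeric(2 * h * w))
  biases <- vapply(units, function(u) u$bias, numeric(1))
  n_per <- max(1, round(n_stim / length(disparities)))
  n_total <- n_per * length(disparities)
  responses <- matrix(NA_real_, n_total, length(units))
  dix <- rep(seq_along(disparities), each = n_per)
  with_seed_if(seed, {
    for (k in seq_along(disparities)) {
      d <- disparities[k]
      base <- matrix(runif(h * (w + 2 * m) * n_per, -1, 1), h)
      li <- as.vector(outer(seq_len(h), (m + (0:(w - 1))) * h, `+`))
      ri <- as.vector(outer(seq_len(h), (m - d + (0:(w - 1))) * h, `+`))
      S <- rbind(matrix(base[li + rep((seq_len(n_per) - 1) * h * (w + 2 * m),
                                      each = h * w)], h * w),
                 matrix(base[ri + rep((seq_len(n_per) - 1) * h * (w + 2 * m),
                                      each = h * w)], h * w))
      drive <- crossprod(S, W) + matrix(biases, n_per, length(units),
                                        byrow = TRUE)
      responses[dix == k, ] <- apply_nonlinearity(drive, nl)
    }
  })
  list(responses = responses, disparity_index = dix)
}

# internal: equal-width quantization + joint conditional histogram
quantize_responses <- function(responses, dix, disparities, bins) {
  n_units <- ncol(responses)
  edges <- vector("list", n_units)
  codes <- rep(1L, nrow(responses))
  mult <- 1L
  for (u in seq_len(n_units)) {
    x <- responses[, u]
    mn <- min(x); mx <- max(x)
    edges[[u]] <- seq(mn, mx, length.out = bins + 1)
    b <- if (mx > mn) pmax(1L, pmin(bins, ceiling((x - mn) / (mx - mn) * bins)))
         else rep(1L, length(x))
    codes <- codes + (b - 1L) * mult
    mult <- mult * bins
  }
  n_cells <- bins^n_units
  cond <- vapply(seq_along(disparities), function(k) {
    tabulate(codes[dix == k], nbins = n_cells) / sum(dix == k)
  }, numeric(n_cells))
  prior <- rep(1 / length(disparities), length(disparities))
  structure(list(cond = cond, marginal = as.vector(cond %*% prior),
                 prior = prior, disparities = disparities, bins = bins,
                 n_units = n_units, bin_edges = edges,
                 n_stim = nrow(responses)),
            class = "response_distribution")
}

#' @export
print.response_distribution <- function(x, ...) {
  cat(sprintf("Response distribution: %d unit(s), %d bins each, %d disparities, %d stimuli\n",
              x$n_units, x$bins, length(x$disparities), x$n_stim))
  invisible(x)
}

#' Specific (Shannon) information about one disparity
#'
#' `I(R, s_d) = sum_i p(r_i | s_d) log2( p(r_i | s_d) / p(r_i) )` -- the KL
#' divergence between the response distribution conditioned on disparity `d`
#' and the marginal, in bits. Zero-probability response bins contribute 0.
#'
#' @param dist A [response_distribution()].
#' @param delta Disparity (must be on the grid); if `NULL`, the full curve
#'   over the grid is returned.
#' @return Bits (scalar, or vector over the grid).
#' @export
specific_information <- function(dist, delta = NULL) {
  stopifnot(inherits(dist, "response_distribution"))
  one <- function(k) {
    p <- dist$cond[, k]
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / dist$marginal[nz]))
  }
  if (is.null(delta)) {
    v <- vapply(seq_along(dist$disparities), one, numeric(1))
    names(v) <- dist$disparities
    return(v)
  }
  k <- match(delta, dist$disparities)
  if (is.na(k)) stop("delta is not on the disparity grid")
  one(k)
}

#' Mutual information between population response and disparity
#'
#' Integrates specific information over the stimulus prior:
#' `I(R, S) = sum_d p(d) I(R, s_d)`, in bits. Bounded above by
#' `log2(number of disparity levels)` for a uniform prior.
#'
#' @param dist A [response_distribution()].
#' @return Bits.
#' @export
population_information <- function(dist) {
  stopifnot(inherits(dist, "response_distribution"))
  sum(dist$prior * specific_information(dist))
}

# internal: binocular Gabor unit for the information analyses; the position
# disparity is split symmetrically between the eyes so the envelope stays
# inside the grid
make_info_unit <- function(dx0 = 0, dphi = 0, sigma = 5, f = 0.05,
                           shape = c(25, 41)) {
  base <- gabor_params(sigma = sigma, freq = f, x0 = -dx0 / 2,
                       phase = wrap_phase(-dphi / 2), theta = pi / 2)
  # vertical truncation at ~2.5 sigma is deliberate (keeps the stimulus
  # grids small); the envelope warning does not apply here
  suppressWarnings(make_binocular_gabor(base, dx0 = dx0, dphi = dphi,
                                        shape = shape))
}

#' Compare position, phase and hybrid population encodings
#'
#' Generates random populations of N simple units in which only the position
#' and/or phase offsets vary (envelope width and spatial frequency fixed),
#' computes the mutual information each population carries about stimulus
#' disparity, and summarizes per encoding: mean and SD over random
#' populations plus the value of a population with uniformly spaced offsets
#' (equally spaced positions over the disparity range, phases over
#' `[-pi, pi)`), which minimizes tuning-curve overlap. One shared stimulus
#' ensemble is used throughout.
#'
#' @param N Units per population.
#' @param n_pop Random populations per encoding.
#' @param disparities Integer disparity grid.
#' @param n_stim Total stimuli in the ensemble.
#' @param bins Response bins per unit.
#' @param sigma,f Shared envelope width (px) and frequency (cyc/px).
#' @param shape RF/stimulus grid shape.
#' @param nl A [nonlinearity()].
#' @param seed Master seed (controls both the ensemble and the populations).
#' @param chunk Populations processed per block (memory control).
#' @return A data frame with one row per encoding: `random_mean`,
#'   `random_sd`, `uniform`, and metadata columns.
#' @export
compare_encodings <- function(N = 5, n_pop = 1000, disparities = -20:20,
                              n_stim = 100000, bins = 10, sigma = 5,
                              f = 0.05, shape = c(25, 41),
                              nl = nonlinearity("rectified-squaring"),
                              seed = 1, chunk = 50) {
  encodings <- c("position", "phase", "hybrid")
  pos_range <- range(disparities)
  draw_offsets <- function(encoding, n) {
    dx0 <- if (encoding != "phase") runif(n, pos_range[1], pos_range[2]) else numeric(n)
    dphi <- if (encoding != "position") runif(n, -pi, pi) else numeric(n)
    list(dx0 = dx0, dphi = dphi)
  }
  uniform_offsets <- function(encoding) {
    upos <- seq(pos_range[1], pos_range[2], length.out = N)
    uphi <- seq(-pi, pi, length.out = N + 1)[seq_len(N)]
    list(dx0 = if (encoding != "phase") upos else numeric(N),
         dphi = if (encoding != "position") uphi else numeric(N))
  }
  info_for_population <- function(resp, dix) {
    population_information(quantize_responses(resp, dix, disparities, bins))
  }
  rows <- lapply(encodings, function(enc) {
    offs <- with_seed_if(seed + match(enc, encodings),
                         draw_offsets(enc, n_pop * N))
    infos <- numeric(n_pop)
    starts <- seq(1, n_pop, by = chunk)
    for (s in starts) {
      pops <- s:min(s + chunk - 1, n_pop)
      uix <- as.vector(outer(seq_len(N), (pops - 1) * N, `+`))
      units <- lapply(uix, function(i)
        make_info_unit(offs$dx0[i], offs$dphi[i], sigma, f, shape))
      r <- unit_responses(units, nl, disparities, n_stim, seed = seed)
      for (j in seq_along(pops)) {
        cols <- (j - 1) * N + seq_len(N)
        infos[pops[j]] <- info_for_population(r$responses[, cols, drop = FALSE],
                                              r$disparity_index)
      }
    }
    uo <- uniform_offsets(enc)
    uunits <- lapply(seq_len(N), function(i)
      make_info_unit(uo$dx0[i], uo$dphi[i], sigma, f, shape))
    ur <- unit_responses(uunits, nl, disparities, n_stim, seed = seed)
    data.frame(encoding = enc, random_mean = mean(infos), random_sd = sd(infos),
               uniform = info_for_population(ur$responses, ur$disparity_index),
               n_pop = n_pop, N = N, bins = bins, n_stim = ur$disparity_index |>
                 length())
  })
  do.call(rbind, rows)
}
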