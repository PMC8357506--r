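# Gaussian scale space and difference-of-Gaussians stack.
#
# The detector searches for blob-like speckle features across scales. Each
# octave holds s + 3 Gaussian layers L(x, y, sigma) with sigma = sigma0 * k^i
# (k = 2^(1/s)) relative to the octave, and the next octave is seeded by
# 2x downsampling of the layer at 2 * sigma0. Adjacent layers are subtracted
# to give the DoG stack D(x, y, sigma) = L(x, y, k sigma) - L(x, y, sigma),
# which approximates the scale-normalized Laplacian.

#' Discrete 2-D Gaussian kernel
#'
#' Samples G(x, y, sigma) = exp(-(x^2 + y^2) / (2 sigma^2)) / (2 pi sigma^2)
#' on an integer grid of half-width `radius` and renormalizes to sum 1.
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @param radius Truncation half-width; defaults to `ceiling(4 * sigma)`.
#' @return A `(2 radius + 1)` square numeric matrix summing to 1.
#' @export
gaussian_kernel_2d <- function(sigma, radius = ceiling(4 * sigma)) {
  if (!is.numeric(sigma) || sigma <= 0) {
    abort("`sigma` must be positive", class = "echotrack_error")
  }
  x <- seq(-radius, radius)
  g1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

# Gaussian smoothing with edge replication; sigma = 0 returns the input.
# The kernel is truncated at 4 sigma, capped so it never exceeds the frame.
smooth_gaussian <- function(frame, sigma) {
  if (sigma <= 0) return(frame)
  radius <- min(ceiling(4 * sigma), floor((min(dim(frame)) - 1) / 2))
  conv2_replicate(frame, gaussian_kernel_2d(sigma, radius = radius))
}

#' Configure the detector's scale space
#'
#' @param sigma0 Base smoothing scale in pixels of the first layer of each
#'   octave.
#' @param scales Number of scales sampled per octave (`s`); the layer scale
#'   ratio is `k = 2^(1/s)` and each octave holds `s + 3` Gaussian layers so
#'   that `s` DoG layers can be searched for extrema.
#' @param octaves Number of octaves, or `NULL` to derive it from the image
#'   size (stopping while the octave is at least 16 px on its short side).
#' @param contrast_threshold Minimum refined |D| for a keypoint to be kept.
#' @param edge_ratio Curvature-ratio bound `r` for edge rejection; keypoints
#'   with `tr(H)^2 / det(H) >= (r + 1)^2 / r` are discarded.
#' @param assumed_blur Blur already present in the input image, in pixels;
#'   the base layer is smoothed by `sqrt(sigma0^2 - assumed_blur^2)`.
#' @param double_input If `TRUE`, upsample the input 2x before building the
#'   pyramid (adds a -1 octave). Off by default.
#' @param abs_response If `TRUE` (default) the contrast gate tests |D|, so
#'   dark blobs (DoG minima) are kept; `FALSE` tests the signed response.
#' @return An object of class `scale_space_config`.
#' @export
scale_space_config <- function(sigma0 = 1.6, scales = 3L, octaves = NULL,
                               contrast_threshold = 0.03, edge_ratio = 10,
                               assumed_blur = 0.5, double_input = FALSE,
                               abs_response = TRUE) {
  if (sigma0 <= 0) abort("`sigma0` must be positive",
                         class = "echotrack_config_error")
  scales <- as.integer(scales)
  if (is.na(scales) || scales < 2) {
    abort("`scales` must be an integer >= 2", class = "echotrack_config_error")
  }
  if (contrast_threshold < 0) {
    abort("`contrast_threshold` must be >= 0",
          class = "echotrack_config_error")
  }
  if (edge_ratio <= 0) abort("`edge_ratio` must be positive",
                             class = "echotrack_config_error")
  structure(
    list(sigma0 = sigma0, scales = scales, octaves = octaves,
         k = 2^(1 / scales), contrast_threshold = contrast_threshold,
         edge_ratio = edge_ratio, assumed_blur = assumed_blur,
         double_input = double_input, abs_response = abs_response),
    class = "scale_space_config"
  )
}

# 2x downsampling by keeping odd-indexed pixels (1, 3, 5, ...).
downsample2 <- function(frame) {
  frame[seq(1, nrow(frame), by = 2), seq(1, ncol(frame), by = 2), drop = FALSE]
}

# 2x upsampling by bilinear interpolation (used when double_input = TRUE).
upsample2 <- function(frame) {
  h <- nrow(frame); w <- ncol(frame)
  rows <- rep(seq(1, h, length.out = 2 * h), times = 2 * w)
  cols <- rep(seq(1, w, length.out = 2 * w), each = 2 * h)
  matrix(bilinear_sample(frame, rows, cols), 2 * h, 2 * w)
}

#' Build the Gaussian scale space of a frame
#'
#' Octave `o` (1-based), layer `i` (1-based) holds the image smoothed to
#' absolute scale `sigma0 * k^(i-1) * 2^(o-1)`; octave `o + 1` starts from a
#' 2x downsampling of octave `o`'s layer at relative scale `2 * sigma0`.
#' Smoothing is incremental: each layer adds `sqrt(sig_i^2 - sig_{i-1}^2)` of
#' blur to the previous one, which equals direct smoothing at `sig_i` by the
#' Gaussian semigroup property.
#'
#' @param frame Numeric matrix in \[0, 1\].
#' @param cfg A [scale_space_config()].
#' @return An object of class `scale_space`: list of octaves, each with
#'   `gauss` (list of matrices), `sigma_rel` (octave-relative scales),
#'   `sigma_abs`, `step` (pixel size relative to the base image), and later
#'   `dog` once [build_dog()] has run.
#' @export
build_scale_space <- function(frame, cfg = scale_space_config()) {
  assert_frame(frame)
  base <- frame
  base_step <- 1
  if (isTRUE(cfg$double_input)) {
    base <- upsample2(base)
    base_step <- 0.5
  }
  nlay <- cfg$scales + 3L
  max_oct <- max(1L, floor(log2(min(dim(base)) / 16)) + 1L)
  octaves_wanted <- if (is.null(cfg$octaves)) max_oct else as.integer(cfg$octaves)
  if (octaves_wanted > max_oct) {
    warn(sprintf("image supports only %d octaves (requested %d)",
                 max_oct, octaves_wanted))
    octaves_wanted <- max_oct
  }
  # reach sigma0 from the assumed input blur
  d0 <- sqrt(max(cfg$sigma0^2 - (cfg$assumed_blur / base_step)^2, 0))
  sig_rel <- cfg$sigma0 * cfg$k^(seq_len(nlay) - 1)
  sig_inc <- sqrt(pmax(sig_rel[-1]^2 - sig_rel[-nlay]^2, 0))
  octaves <- vector("list", octaves_wanted)
  cur <- smooth_gaussian(base, d0)
  for (o in seq_len(octaves_wanted)) {
    gauss <- vector("list", nlay)
    gauss[[1]] <- cur
    for (i in 2:nlay) gauss[[i]] <- smooth_gaussian(gauss[[i - 1]], sig_inc[i - 1])
    octaves[[o]] <- list(gauss = gauss, sigma_rel = sig_rel,
                         sigma_abs = sig_rel * 2^(o - 1) * base_step,
                         step = base_step * 2^(o - 1))
    if (o < octaves_wanted) {
      # the layer at relative scale 2 * sigma0 is index scales + 1
      cur <- downsample2(gauss[[cfg$scales + 1L]])
    }
  }
  structure(list(octaves = octaves, cfg = cfg, dim = dim(frame)),
            class = "scale_space")
}

#' Fill the difference-of-Gaussians stack of a scale space
#'
#' DoG layer `i` of each octave is the exact elementwise difference
#' `L(., ., k^i sigma) - L(., ., k^(i-1) sigma)` of adjacent Gaussian layers,
#' giving one fewer DoG than Gaussian layer per octave.
#'
#' @param space A [build_scale_space()] result.
#' @return The same `scale_space` with `dog` filled in each octave.
#' @export
build_dog <- function(space) {
  stopifnot(inherits(space, "scale_space"))
  space$octaves <- lapply(space$octaves, function(oct) {
    n <- length(oct$gauss)
    oct$dog <- lapply(seq_len(n - 1), function(i) oct$gauss[[i + 1]] - oct$gauss[[i]])
    oct
  })
  space
}

#' @export
print.scale_space <- function(x, ...) {
  cat(sprintf("<scale_space> %d octave(s), %d Gaussian layers each, sigma0 = %g\n",
              length(x$octaves), length(x$octaves[[1]]$gauss), x$cfg$sigma0))
  invisible(x)
}
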