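# 128-dimensional rotation-invariant descriptors.
#
# Gradients are sampled over a circular window of radius
# R = (3 sigma sqrt(2) (d + 1) + 1) / 2 around the keypoint, sample offsets
# are rotated by minus the keypoint orientation so the descriptor is
# expressed in the keypoint's own frame, and magnitudes are accumulated into
# a d x d spatial grid of 8-bin orientation histograms with trilinear
# interpolation and Gaussian spatial weighting. The flattened d * d * 8
# vector (128 for d = 4) is clamped and normalized.

#' Configure descriptor generation
#'
#' @param d Subregions per side of the spatial grid (default 4).
#' @param bins Orientation bins per subregion (default 8); `d^2 * bins` is
#'   the descriptor length, 128 for the defaults.
#' @param clamp_value Entries of the normalized vector are clamped at this
#'   value and the vector renormalized, which damps single dominant
#'   gradients under illumination change; `NULL` disables clamping.
#' @param normalization `"euclidean"` (unit L2 norm, the form Euclidean
#'   matching presumes) or `"sum"` (divide by the plain sum of entries).
#' @return An object of class `descriptor_config`.
#' @export
descriptor_config <- function(d = 4L, bins = 8L, clamp_value = 0.2,
                              normalization = c("euclidean", "sum")) {
  d <- as.integer(d); bins <- as.integer(bins)
  if (is.na(d) || d < 1) abort("`d` must be >= 1",
                               class = "echotrack_config_error")
  if (is.na(bins) || bins < 1) abort("`bins` must be >= 1",
                                     class = "echotrack_config_error")
  if (!is.null(clamp_value) && clamp_value <= 0) {
    abort("`clamp_value` must be positive or NULL",
          class = "echotrack_config_error")
  }
  structure(list(d = d, bins = bins, clamp_value = clamp_value,
                 normalization = match.arg(normalization)),
            class = "descriptor_config")
}

#' Radius of the circular descriptor window
#'
#' `R = ceiling((3 sigma sqrt(2) (d + 1) + 1) / 2)` in octave-local pixels:
#' the enclosing radius of a d x d grid of subregions 3 sigma wide, allowing
#' for rotation (the sqrt(2) factor) and bilinear spill (the +1).
#'
#' @param sigma Octave-relative keypoint scale (> 0).
#' @param d Subregions per side.
#' @return Integer radius in pixels.
#' @export
descriptor_radius <- function(sigma, d = 4L) {
  if (sigma <= 0) abort("`sigma` must be positive", class = "echotrack_error")
  as.integer(ceiling((3 * sigma * sqrt(2) * (d + 1) + 1) / 2))
}

#' Rotate (drow, dcol) offsets
#'
#' Standard 2-D rotation by `alpha`, counterclockwise with the column axis as
#' abscissa and the row axis as ordinate — the same angle convention as
#' [assign_orientation()].
#'
#' @param offset Numeric `c(drow, dcol)` or a 2-column matrix of offsets.
#' @param alpha Rotation angle in radians.
#' @return Rotated offset(s) in the same shape.
#' @export
rotate_coords <- function(offset, alpha) {
  if (is.null(dim(offset))) offset <- matrix(offset, ncol = 2)
  dr <- offset[, 1]; dc <- offset[, 2]
  out <- cbind(sin(alpha) * dc + cos(alpha) * dr,
               cos(alpha) * dc - sin(alpha) * dr)
  colnames(out) <- c("drow", "dcol")
  if (nrow(out) == 1) out <- drop(out)
  out
}

#' Normalize a raw descriptor vector
#'
#' `mode = "sum"` divides each entry by the plain sum of entries
#' (`l_j = w_j / sum_i w_i`); `mode = "euclidean"` divides by the L2 norm.
#'
#' @param raw Non-negative numeric vector with at least one positive entry.
#' @param mode `"euclidean"` or `"sum"`.
#' @return Normalized vector.
#' @export
normalize_descriptor <- function(raw, mode = c("euclidean", "sum")) {
  mode <- match.arg(mode)
  s <- if (mode == "sum") sum(raw) else sqrt(sum(raw^2))
  if (!is.finite(s) || s <= 0) {
    abort("degenerate descriptor: all entries zero",
          class = "echotrack_error")
  }
  raw / s
}

#' Compute the descriptor of one oriented keypoint
#'
#' @param space A `scale_space`.
#' @param kp A one-row data frame (or list) with fields `octave`, `layer`,
#'   `row_oct`, `col_oct`, `sigma_oct`, `orientation` as produced by
#'   [detect_keypoints()].
#' @param cfg A [descriptor_config()].
#' @param grads Optional precomputed [layer_gradients()] of the keypoint's
#'   Gaussian layer.
#' @return Numeric vector of length `d^2 * bins`, or `NULL` with attribute-
#'   free failure when the window exits the image or all gradients vanish
#'   (callers treat `NULL` as "skipped").
#' @export
compute_descriptor <- function(space, kp, cfg = descriptor_config(),
                               grads = NULL) {
  oct <- space$octaves[[kp$octave]]
  img <- oct$gauss[[kp$layer]]
  if (is.null(grads)) grads <- layer_gradients(img)
  h <- nrow(img); w <- ncol(img)
  d <- cfg$d; nbins <- cfg$bins
  width <- 3 * kp$sigma_oct          # subregion width in pixels
  radius <- descriptor_radius(kp$sigma_oct, d)
  r0 <- round(kp$row_oct); c0 <- round(kp$col_oct)
  if (r0 - radius < 2 || r0 + radius > h - 1 ||
      c0 - radius < 2 || c0 + radius > w - 1) {
    return(NULL)                     # window exits the image: skip
  }
  dr <- rep(seq(-radius, radius), times = 2 * radius + 1)
  dc <- rep(seq(-radius, radius), each = 2 * radius + 1)
  keep <- dr^2 + dc^2 <= radius^2
  dr <- dr[keep]; dc <- dc[keep]
  rot <- rotate_coords(cbind(dr, dc), -kp$orientation)
  u <- rot[, 1] / width + d / 2 - 0.5   # row bin coordinate
  v <- rot[, 2] / width + d / 2 - 0.5   # col bin coordinate
  keep <- u > -1 & u < d & v > -1 & v < d
  if (!any(keep)) return(NULL)
  dr <- dr[keep]; dc <- dc[keep]; u <- u[keep]; v <- v[keep]
  ij <- cbind(r0 + dr, c0 + dc)
  grow <- grads$grow[ij]; gcol <- grads$gcol[ij]
  m <- sqrt(grow^2 + gcol^2)
  if (max(m) <= 1e-12) return(NULL)  # flat window (up to convolution noise)
  theta <- (atan2(grow, gcol) - kp$orientation) %% (2 * pi)
  obin <- theta / (2 * pi / nbins)    # continuous in [0, nbins)
  # Gaussian spatial weight, sigma = d/2 subregion widths, on unrotated radii
  wgt <- m * exp(-(dr^2 + dc^2) / (2 * (0.5 * d * width)^2))
  u0 <- floor(u); v0 <- floor(v); o0 <- floor(obin)
  fu <- u - u0; fv <- v - v0; fo <- obin - o0
  hist <- numeric(d * d * nbins)
  for (du in 0:1) for (dv in 0:1) for (do in 0:1) {
    ui <- u0 + du; vi <- v0 + dv
    ok <- ui >= 0 & ui <= d - 1 & vi >= 0 & vi <= d - 1
    if (!any(ok)) next
    oi <- (o0[ok] + do) %% nbins
    wk <- wgt[ok] *
      (if (du == 1) fu[ok] else 1 - fu[ok]) *
      (if (dv == 1) fv[ok] else 1 - fv[ok]) *
      (if (do == 1) fo[ok] else 1 - fo[ok])
    idx <- ui[ok] * d * nbins + vi[ok] * nbins + oi + 1
    acc <- rowsum(wk, idx)
    ii <- as.integer(rownames(acc))
    hist[ii] <- hist[ii] + acc[, 1]
  }
  if (sum(hist) == 0) return(NULL)
  vec <- normalize_descriptor(hist, cfg$normalization)
  if (!is.null(cfg$clamp_value)) {
    vec <- pmin(vec, cfg$clamp_value)
    vec <- normalize_descriptor(vec, cfg$normalization)
  }
  vec
}

#' Compute descriptors for a keypoint table
#'
#' @param space A `scale_space` of the frame the keypoints came from.
#' @param keypoints Tibble from [detect_keypoints()].
#' @param cfg A [descriptor_config()].
#' @return The keypoint tibble restricted to keypoints whose window fits the
#'   image, with a matrix column `desc` (`n x 128` for defaults).
#' @export
compute_descriptors <- function(space, keypoints, cfg = descriptor_config()) {
  stopifnot(inherits(space, "scale_space"))
  n <- nrow(keypoints)
  len <- cfg$d^2 * cfg$bins
  if (n == 0) {
    out <- keypoints
    out$desc <- matrix(numeric(0), 0, len)
    return(out)
  }
  grad_cache <- new.env(parent = emptyenv())
  mat <- matrix(NA_real_, n, len)
  for (i in seq_len(n)) {
    kp <- keypoints[i, ]
    key <- sprintf("%d_%d", kp$octave, kp$layer)
    if (is.null(grad_cache[[key]])) {
      grad_cache[[key]] <-
        layer_gradients(space$octaves[[kp$octave]]$gauss[[kp$layer]])
    }
    v <- compute_descriptor(space, kp, cfg, grads = grad_cache[[key]])
    if (!is.null(v)) mat[i, ] <- v
  }
  ok <- !is.na(mat[, 1])
  out <- keypoints[ok, , drop = FALSE]
  out$desc <- mat[ok, , drop = FALSE]
  out
}

#' Detect keypoints and compute their descriptors in one call
#'
#' Convenience wrapper chaining [build_scale_space()], [build_dog()],
#' [detect_keypoints()] and [compute_descriptors()], optionally despeckling
#' the frame first with [mean_filter()].
#'
#' @param frame Numeric matrix in \[0, 1\].
#' @param cfg A [scale_space_config()].
#' @param desc_cfg A [descriptor_config()].
#' @param denoise `NULL`, or a [mean_filter_spec()] applied before detection.
#' @return Keypoint tibble with a `desc` matrix column (see
#'   [compute_descriptors()]).
#' @export
sift_features <- function(frame, cfg = scale_space_config(),
                          desc_cfg = descriptor_config(), denoise = NULL) {
  if (!is.null(denoise)) frame <- mean_filter(frame, denoise)
  space <- build_dog(build_scale_space(frame, cfg))
  kps <- detect_keypoints(frame, cfg, space = space)
  compute_descriptors(space, kps, desc_cfg)
}
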