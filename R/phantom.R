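# Synthetic speckle phantoms with known ground-truth motion.
#
# Ultrasound B-mode images carry a granular interference texture (speckle)
# that moves with the tissue, so a phantom made of randomly placed bright
# scatterers smoothed by a point-spread blur is a usable stand-in for testing
# a speckle tracker: every frame is derived from frame 0 by a known
# displacement field, which downstream stages must recover.

#' Specify a synthetic speckle phantom
#'
#' @param height,width Frame size in pixels (each at least 32 unless
#'   `strict = FALSE`).
#' @param speckle_density Fraction of pixels seeded with a bright scatterer,
#'   in \[0, 1) (0 gives an empty frame).
#' @param blur_sigma Standard deviation in pixels of the Gaussian point-spread
#'   smoothing applied to the scatterer field; 0 disables blurring.
#' @param noise_kind One of `"none"`, `"gaussian"` (additive), `"salt_pepper"`
#'   (replacement), `"speckle"` (multiplicative).
#' @param noise_level Noise strength: standard deviation for `gaussian` and
#'   `speckle`, corrupted-pixel fraction for `salt_pepper`. Must be >= 0.
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   phantom.
#' @param strict If `TRUE` (default) enforce the minimum 32-pixel frame size.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height, width, speckle_density = 0.15,
                         blur_sigma = 1, noise_kind = "none",
                         noise_level = 0, seed = 1L, strict = TRUE) {
  height <- as.integer(height); width <- as.integer(width)
  min_dim <- if (strict) 32L else 1L
  if (is.na(height) || is.na(width) || height < min_dim || width < min_dim) {
    abort(sprintf("frame dimensions must be at least %d pixels", min_dim),
          class = "echotrack_config_error")
  }
  if (!is.numeric(speckle_density) || speckle_density < 0 ||
      speckle_density >= 1) {
    abort("`speckle_density` must lie in [0, 1)",
          class = "echotrack_config_error")
  }
  if (blur_sigma < 0) {
    abort("`blur_sigma` must be >= 0", class = "echotrack_config_error")
  }
  noise_kind <- match.arg(noise_kind,
                          c("none", "gaussian", "salt_pepper", "speckle"))
  if (noise_level < 0) {
    abort("`noise_level` must be >= 0", class = "echotrack_config_error")
  }
  structure(
    list(height = height, width = width, speckle_density = speckle_density,
         blur_sigma = blur_sigma, noise_kind = noise_kind,
         noise_level = noise_level, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate one speckle frame from a phantom spec
#'
#' Seeds `speckle_density * height * width` pixels (in expectation) with
#' scatterer amplitudes drawn uniformly from (0.25, 1], then smooths with a
#' Gaussian point-spread of `blur_sigma` pixels. Intensities stay in \[0, 1\].
#'
#' @param spec A [phantom_spec()].
#' @param offset Optional exact subpixel translation `c(drow, dcol)`: the
#'   same scatterer field is rendered with the point-spread centers moved by
#'   `offset`, so the result is the base frame translated without any
#'   resampling blur (requires `blur_sigma > 0`). Useful as ground truth for
#'   subpixel flow oracles.
#' @return A `height x width` numeric matrix in \[0, 1\].
#' @export
make_speckle_frame <- function(spec, offset = c(0, 0)) {
  stopifnot(inherits(spec, "phantom_spec"))
  frame <- withr::with_seed(spec$seed, {
    hit <- stats::runif(spec$height * spec$width) < spec$speckle_density
    amp <- stats::runif(spec$height * spec$width, 0.25, 1)
    matrix(ifelse(hit, amp, 0), spec$height, spec$width)
  })
  shifted <- any(offset != 0)
  if (shifted && spec$blur_sigma <= 0) {
    abort("subpixel `offset` rendering requires blur_sigma > 0",
          class = "echotrack_config_error")
  }
  if (spec$blur_sigma > 0) {
    radius <- ceiling(4 * spec$blur_sigma + max(abs(offset)))
    base <- conv2_replicate(frame,
                            gaussian_kernel_2d(spec$blur_sigma, radius))
    # contrast-stretch to the display range, as B-mode frames are; the
    # shifted render reuses the base normalization so intensities match
    mx <- max(base)
    if (!shifted) {
      frame <- if (mx > 0) base / mx else base
    } else {
      x <- seq(-radius, radius)
      kr <- exp(-(x - offset[1])^2 / (2 * spec$blur_sigma^2))
      kc <- exp(-(x - offset[2])^2 / (2 * spec$blur_sigma^2))
      k0 <- gaussian_kernel_2d(spec$blur_sigma, radius)
      k <- outer(kr, kc) * sum(k0) / sum(outer(kr, kc)) # match base mass
      frame <- conv2_replicate(frame, k)
      if (mx > 0) frame <- frame / mx
    }
  }
  clip01(frame)
}

#' Describe frame-to-frame motion for a phantom sequence
#'
#' Three motion families cover the components of cardiac wall motion a
#' speckle tracker must follow: rigid translation, rotation about a center
#' (torsion), and a periodic radial contraction/relaxation cycle emulating
#' systole and diastole.
#'
#' @param kind `"translation"`, `"rotation"`, or `"periodic_radial"`.
#' @param shift Per-frame translation `c(drow, dcol)` in pixels
#'   (`translation` only).
#' @param degrees Per-frame rotation angle in degrees (`rotation` only).
#' @param center Rotation / contraction center `c(row, col)`; defaults to the
#'   frame center when the field is evaluated.
#' @param amplitude Peak inward displacement in pixels, reached at half a
#'   period, for a point on the inscribed-circle boundary
#'   (`periodic_radial` only).
#' @param period Cycle length in frames (`periodic_radial` only).
#'
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(kind = c("translation", "rotation", "periodic_radial"),
                         shift = c(0, 0), degrees = 0, center = NULL,
                         amplitude = 0, period = 20) {
  kind <- match.arg(kind)
  if (kind == "translation" && length(shift) != 2) {
    abort("`shift` must be c(drow, dcol)", class = "echotrack_config_error")
  }
  if (kind == "periodic_radial" && period <= 0) {
    abort("`period` must be positive", class = "echotrack_config_error")
  }
  structure(
    list(kind = kind, shift = as.numeric(shift), degrees = as.numeric(degrees),
         center = if (!is.null(center)) as.numeric(center),
         amplitude = as.numeric(amplitude), period = as.numeric(period)),
    class = "motion_model"
  )
}

model_center <- function(model, height, width) {
  if (!is.null(model$center)) model$center else c((height + 1) / 2, (width + 1) / 2)
}

# Radial scale factor at time t: 1 at t = 0, maximal contraction at t =
# period / 2, back to 1 at t = period. `amplitude` is calibrated so a point
# at the inscribed-circle radius moves exactly `amplitude` px at peak.
radial_scale <- function(model, t, height, width) {
  rho_max <- min(height, width) / 2
  1 - (model$amplitude / rho_max) * (1 - cos(2 * pi * t / model$period)) / 2
}

#' Evaluate a motion model as a dense displacement field
#'
#' Fields are cumulative, referenced to frame 0 (time `t = 0` gives a zero
#' field). Two directions are available: `"forward"` gives the displacement
#' of the material point that sits at each grid position in frame 0 (the
#' ground truth a tracker should recover); `"pull"` gives, at each frame-`t`
#' grid position, the offset back to its source in frame 0, which is what
#' [warp_frame()] consumes.
#'
#' @param model A [motion_model()].
#' @param t Frame time (0-based; frame 1 of a sequence is `t = 0`).
#' @param height,width Field dimensions.
#' @param type `"forward"` or `"pull"`.
#' @return A list with matrices `drow` and `dcol`.
#' @export
motion_field <- function(model, t, height, width,
                         type = c("forward", "pull")) {
  stopifnot(inherits(model, "motion_model"))
  type <- match.arg(type)
  rows <- matrix(rep(seq_len(height), width), height, width)
  cols <- matrix(rep(seq_len(width), each = height), height, width)
  zero <- matrix(0, height, width)
  if (model$kind == "translation") {
    return(list(drow = zero + t * model$shift[1],
                dcol = zero + t * model$shift[2]))
  }
  ctr <- model_center(model, height, width)
  pr <- rows - ctr[1]; pc <- cols - ctr[2]
  if (model$kind == "rotation") {
    ang <- t * model$degrees * pi / 180
    if (type == "pull") ang <- -ang
    # rotate (col, row) by ang, CCW with col as abscissa and row as ordinate
    nr <- sin(ang) * pc + cos(ang) * pr
    nc <- cos(ang) * pc - sin(ang) * pr
    if (type == "forward") {
      list(drow = nr - pr, dcol = nc - pc)
    } else {
      list(drow = pr - nr, dcol = pc - nc)
    }
  } else { # periodic_radial
    s <- radial_scale(model, t, height, width)
    if (type == "forward") {
      list(drow = (s - 1) * pr, dcol = (s - 1) * pc)
    } else {
      list(drow = pr * (1 - 1 / s), dcol = pc * (1 - 1 / s))
    }
  }
}

#' Apply a motion model to individual points
#'
#' Forward-maps frame-0 positions to their ground-truth positions at time
#' `t`, without rasterizing a dense field.
#'
#' @param model A [motion_model()].
#' @param t Frame time (0-based).
#' @param points A data frame with columns `row`, `col` (frame-0 positions).
#' @param height,width Frame dimensions (needed for the default center and
#'   the radial calibration).
#' @return A tibble with columns `row`, `col` of positions at time `t`.
#' @export
motion_apply <- function(model, t, points, height, width) {
  stopifnot(inherits(model, "motion_model"))
  r <- points$row; c_ <- points$col
  if (model$kind == "translation") {
    return(tibble(row = r + t * model$shift[1], col = c_ + t * model$shift[2]))
  }
  ctr <- model_center(model, height, width)
  pr <- r - ctr[1]; pc <- c_ - ctr[2]
  if (model$kind == "rotation") {
    ang <- t * model$degrees * pi / 180
    tibble(row = ctr[1] + sin(ang) * pc + cos(ang) * pr,
           col = ctr[2] + cos(ang) * pc - sin(ang) * pr)
  } else {
    s <- radial_scale(model, t, height, width)
    tibble(row = ctr[1] + s * pr, col = ctr[2] + s * pc)
  }
}

#' Warp a frame by a dense displacement field
#'
#' Resamples the frame so that output pixel `(r, c)` takes the intensity at
#' `(r - drow(r, c), c - dcol(r, c))` in the input. Out-of-frame samples
#' replicate the nearest edge pixel. With a pull-direction field from
#' [motion_field()], this renders frame `t` from frame 0.
#'
#' @param frame Numeric matrix.
#' @param field List with matrices `drow`, `dcol` matching `dim(frame)`.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return Warped frame, same dimensions.
#' @export
warp_frame <- function(frame, field, interpolation = c("bilinear", "nearest")) {
  assert_frame(frame)
  interpolation <- match.arg(interpolation)
  if (!identical(dim(field$drow), dim(frame)) ||
      !identical(dim(field$dcol), dim(frame))) {
    abort("displacement field dimensions must match the frame",
          class = "echotrack_error")
  }
  h <- nrow(frame); w <- ncol(frame)
  rows <- matrix(rep(seq_len(h), w), h, w) - field$drow
  cols <- matrix(rep(seq_len(w), each = h), h, w) - field$dcol
  if (interpolation == "nearest") {
    rows <- pmin(pmax(round(rows), 1), h)
    cols <- pmin(pmax(round(cols), 1), w)
    out <- frame[cbind(as.vector(rows), as.vector(cols))]
  } else {
    out <- bilinear_sample(frame, as.vector(rows), as.vector(cols))
  }
  matrix(out, h, w)
}

#' Add noise to a frame
#'
#' @param frame Numeric matrix in \[0, 1\].
#' @param kind `"none"`, `"gaussian"`, `"salt_pepper"`, or `"speckle"`.
#' @param level Noise strength (see [phantom_spec()]).
#' @param seed Integer seed.
#' @return Noisy frame, clipped to \[0, 1\].
#' @export
add_noise <- function(frame, kind, level, seed = 1L) {
  assert_frame(frame)
  kind <- match.arg(kind, c("none", "gaussian", "salt_pepper", "speckle"))
  if (level < 0) abort("`level` must be >= 0", class = "echotrack_error")
  if (kind == "none" || level == 0) return(frame)
  n <- length(frame)
  out <- withr::with_seed(as.integer(seed), {
    switch(kind,
      gaussian = frame + stats::rnorm(n, 0, level),
      speckle = frame * (1 + stats::rnorm(n, 0, level)),
      salt_pepper = {
        hit <- stats::runif(n) < level
        salt <- stats::runif(n) < 0.5
        f <- frame
        f[hit & salt] <- 1
        f[hit & !salt] <- 0
        f
      })
  })
  clip01(matrix(out, nrow(frame), ncol(frame)))
}

#' Generate a phantom image sequence with ground truth
#'
#' Frame `t` is `noise(warp(frame0, field_t))` where `field_t` is the
#' cumulative displacement of the motion model at time `t` (frame 1 is
#' `t = 0`, so it differs from the base frame only by noise).
#'
#' @param spec A [phantom_spec()].
#' @param motion A [motion_model()].
#' @param n_frames Number of frames (>= 2).
#' @return An object of class `echo_sequence`: a list with `frames` (list of
#'   matrices), `fields` (list of forward ground-truth displacement fields,
#'   one per frame), `spec`, and `motion`.
#' @export
make_sequence <- function(spec, motion, n_frames) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(motion, "motion_model"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2) {
    abort("`n_frames` must be at least 2", class = "echotrack_config_error")
  }
  base <- make_speckle_frame(spec)
  frames <- vector("list", n_frames)
  fields <- vector("list", n_frames)
  for (t in seq_len(n_frames) - 1L) {
    pull <- motion_field(motion, t, spec$height, spec$width, type = "pull")
    ft <- if (t == 0L) base else warp_frame(base, pull)
    ft <- add_noise(ft, spec$noise_kind, spec$noise_level,
                    seed = spec$seed + t)
    frames[[t + 1L]] <- ft
    fields[[t + 1L]] <- motion_field(motion, t, spec$height, spec$width,
                                     type = "forward")
  }
  structure(list(frames = frames, fields = fields, spec = spec,
                 motion = motion),
            class = "echo_sequence")
}

#' @export
print.echo_sequence <- function(x, ...) {
  cat(sprintf("<echo_sequence> %d frames of %d x %d, motion: %s\n",
              length(x$frames), x$spec$height, x$spec$width, x$motion$kind))
  invisible(x)
}
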