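# Weighted iterative Lucas-Kanade flow, run coarse-to-fine over an image
# pyramid.
#
# For a patch S centered on a point, the displacement b minimizing
# sum_{x in S} |F(x) - G(x + b)| is found by iterating the linearized update
# with per-pixel inverse-residual weights w(x) = 1 / max(|residual|, eps),
# re-evaluated at the current estimate each iteration: pixels still
# violating brightness constancy (noise, decorrelated speckle, occlusion)
# are downweighted, and the weights flatten as the estimate converges, so
# the scheme behaves like iteratively reweighted L1 minimization. The update
# is written in one dimension in terms of the image derivative F'; the 2-D
# lift used here solves the LK weighted least-squares normal equations with
# the spatial gradient vector, keeping the same residual weighting. Large
# motions are handled by estimating at the coarsest pyramid level first and
# feeding 2x the result to the next finer level as the initial value.

#' Configure Lucas-Kanade refinement
#'
#' @param window Patch half-width `S` in pixels (the window is
#'   `(2S+1) x (2S+1)`).
#' @param max_iterations Iteration cap per pyramid level.
#' @param convergence_tol Stop when the update step falls below this many
#'   pixels.
#' @param weight_epsilon Floor on the absolute residual in the weight
#'   denominator, in intensity units; keeps weights bounded where the frames
#'   agree.
#' @param pyramid_levels Number of pyramid levels for [pyramid_flow()].
#' @return An object of class `lk_config`.
#' @export
lk_config <- function(window = 7L, max_iterations = 20L,
                      convergence_tol = 0.01, weight_epsilon = 1e-3,
                      pyramid_levels = 3L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1) abort("`window` must be >= 1",
                                         class = "echotrack_config_error")
  if (max_iterations < 1) abort("`max_iterations` must be >= 1",
                                class = "echotrack_config_error")
  if (convergence_tol <= 0) abort("`convergence_tol` must be positive",
                                  class = "echotrack_config_error")
  if (pyramid_levels < 1) abort("`pyramid_levels` must be >= 1",
                                class = "echotrack_config_error")
  structure(list(window = window, max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 weight_epsilon = weight_epsilon,
                 pyramid_levels = as.integer(pyramid_levels)),
            class = "lk_config")
}

#' Single-level weighted iterative LK refinement
#'
#' Estimates the displacement `b` such that the feature at `point` in
#' `frame_f` sits at `point + b` in `frame_g`, iterating the weighted
#' least-squares update from the starting value `b0`. Subpixel intensities
#' are sampled bilinearly and gradients by central differences at the warped
#' position.
#'
#' @param frame_f,frame_g Numeric matrices of equal dimension.
#' @param point `c(row, col)`, possibly fractional.
#' @param b0 Initial displacement `c(drow, dcol)`.
#' @param cfg An [lk_config()].
#' @return A `flow_estimate`: list with `b` (displacement in pixels),
#'   `iterations_used`, `converged`, and `residual` (weighted mean absolute
#'   intensity difference at the solution).
#' @export
lk_refine <- function(frame_f, frame_g, point, b0 = c(0, 0),
                      cfg = lk_config()) {
  assert_frame(frame_f, "frame_f"); assert_frame(frame_g, "frame_g")
  if (!identical(dim(frame_f), dim(frame_g))) {
    abort("frames must have equal dimensions", class = "echotrack_error")
  }
  h <- nrow(frame_f); w <- ncol(frame_f)
  S <- cfg$window
  pr <- point[1]; pc <- point[2]
  if (pr - S < 1 || pr + S > h || pc - S < 1 || pc + S > w) {
    abort("out of bounds: LK patch leaves the frame",
          class = "echotrack_oob_error")
  }
  off <- seq(-S, S)
  xr <- pr + rep(off, times = 2 * S + 1)
  xc <- pc + rep(off, each = 2 * S + 1)
  fvals <- bilinear_sample(frame_f, xr, xc)
  b <- as.numeric(b0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(cfg$max_iterations)) {
    iters <- it
    yr <- xr + b[1]; yc <- xc + b[2]
    gv <- bilinear_sample(frame_g, yr, yc)
    gr <- (bilinear_sample(frame_g, yr + 1, yc) -
           bilinear_sample(frame_g, yr - 1, yc)) / 2
    gc_ <- (bilinear_sample(frame_g, yr, yc + 1) -
            bilinear_sample(frame_g, yr, yc - 1)) / 2
    resid <- fvals - gv
    # inverse-residual weights, re-evaluated at the current estimate: pixels
    # still violating brightness constancy are downweighted, and the weights
    # flatten out as the estimate converges
    wgt <- 1 / pmax(abs(resid), cfg$weight_epsilon)
    a11 <- sum(wgt * gr * gr); a12 <- sum(wgt * gr * gc_)
    a22 <- sum(wgt * gc_ * gc_)
    if (!is.finite(a11 + a12 + a22) || a11 + a22 <= 0) {
      break  # no usable gradient in the patch
    }
    r1 <- sum(wgt * gr * resid); r2 <- sum(wgt * gc_ * resid)
    # pseudo-inverse of the normal matrix: a patch whose gradients all point
    # one way (e.g. a pure ramp) still yields the step along that direction
    eg <- eigen(matrix(c(a11, a12, a12, a22), 2, 2), symmetric = TRUE)
    ok_ev <- eg$values > 1e-9 * eg$values[1]
    if (!any(ok_ev)) break
    inv_ev <- ifelse(ok_ev, 1 / pmax(eg$values, 1e-300), 0)
    delta <- as.numeric(eg$vectors %*% (inv_ev *
                                          crossprod(eg$vectors, c(r1, r2))))
    b <- b + delta
    if (sqrt(sum(delta^2)) < cfg$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  gv <- bilinear_sample(frame_g, xr + b[1], xc + b[2])
  wgt <- 1 / pmax(abs(fvals - gv), cfg$weight_epsilon)
  structure(list(b = b, iterations_used = iters, converged = converged,
                 residual = sum(wgt * abs(gv - fvals)) / sum(wgt)),
            class = "flow_estimate")
}

#' Build the LK image pyramid
#'
#' Level 1 is the original frame; level `l` pixel `(x, y)` combines level
#' `l - 1` pixels around `(2x - 1, 2y - 1)` with weights 1/4 (center),
#' 1/8 (the 4 edge neighbors) and 1/16 (the 4 diagonal neighbors), which sum
#' to 1. Borders replicate edges; each level has `ceiling(half)` the linear
#' size of the previous.
#'
#' @param frame Numeric matrix.
#' @param levels Number of levels (frame must be at least `2^levels` pixels
#'   per side).
#' @return An object of class `lk_pyramid`: list of matrices.
#' @export
build_lk_pyramid <- function(frame, levels) {
  assert_frame(frame)
  levels <- as.integer(levels)
  if (min(dim(frame)) < 2^levels) {
    abort("too many pyramid levels for this frame size",
          class = "echotrack_config_error")
  }
  pyr <- vector("list", levels)
  pyr[[1]] <- frame
  for (l in seq_len(levels - 1L)) {
    prev <- pyr[[l]]
    h <- nrow(prev); w <- ncol(prev)
    pad <- prev[c(1, 1:h, h), c(1, 1:w, w)]
    oi <- 2 * seq_len(ceiling(h / 2)) - 1  # centers in prev coordinates
    oj <- 2 * seq_len(ceiling(w / 2)) - 1
    ctr <- pad[oi + 1, oj + 1, drop = FALSE]
    up <- pad[oi, oj + 1, drop = FALSE];  dn <- pad[oi + 2, oj + 1, drop = FALSE]
    lf <- pad[oi + 1, oj, drop = FALSE];  rt <- pad[oi + 1, oj + 2, drop = FALSE]
    ul <- pad[oi, oj, drop = FALSE];      ur <- pad[oi, oj + 2, drop = FALSE]
    dl <- pad[oi + 2, oj, drop = FALSE];  dr <- pad[oi + 2, oj + 2, drop = FALSE]
    pyr[[l + 1]] <- ctr / 4 + (up + dn + lf + rt) / 8 + (ul + ur + dl + dr) / 16
  }
  structure(pyr, class = "lk_pyramid")
}

#' Coarse-to-fine pyramid LK flow at a point
#'
#' Runs [lk_refine()] at the coarsest level starting from `b0` scaled to that
#' level, then doubles each level's estimate as the initial value of the next
#' finer level. A level where refinement fails (patch out of bounds,
#' degenerate gradient) falls back to the doubled coarser estimate and the
#' final result is flagged unconverged.
#'
#' @param frame_f,frame_g Numeric matrices of equal dimension.
#' @param point `c(row, col)` in `frame_f` (base resolution).
#' @param cfg An [lk_config()]; `cfg$pyramid_levels` sets the hierarchy
#'   depth.
#' @param b0 Initial displacement guess at base resolution.
#' @return A `flow_estimate` (see [lk_refine()]) at base resolution, with
#'   `iterations_used` summed over levels and `level_failed` counting
#'   fallbacks.
#' @export
pyramid_flow <- function(frame_f, frame_g, point, cfg = lk_config(),
                         b0 = c(0, 0)) {
  L <- cfg$pyramid_levels
  pf <- build_lk_pyramid(frame_f, L)
  pg <- build_lk_pyramid(frame_g, L)
  b <- as.numeric(b0) / 2^(L - 1)
  total_iters <- 0L
  failed <- 0L
  est <- NULL
  for (l in seq(L, 1)) {
    pt_l <- (point - 1) / 2^(l - 1) + 1
    est <- tryCatch(
      lk_refine(pf[[l]], pg[[l]], pt_l, b0 = b, cfg = cfg),
      echotrack_oob_error = function(e) NULL
    )
    if (is.null(est)) {
      failed <- failed + 1L
    } else {
      b <- est$b
      total_iters <- total_iters + est$iterations_used
    }
    if (l > 1) b <- 2 * b
  }
  if (is.null(est)) {
    est <- structure(list(b = b, iterations_used = total_iters,
                          converged = FALSE, residual = NA_real_),
                     class = "flow_estimate")
  }
  est$b <- b
  est$iterations_used <- total_iters
  est$converged <- est$converged && failed == 0L
  est$level_failed <- failed
  est
}

#' @export
print.flow_estimate <- function(x, ...) {
  cat(sprintf("<flow_estimate> b = (%.4f, %.4f) px, %d iteration(s), %s\n",
              x$b[1], x$b[2], x$iterations_used,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
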