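# Keypoint detection in the DoG stack: extremum search over the
# 26-neighborhood, subpixel refinement by a fitted 3-D quadratic, the
# contrast gate on the refined response, curvature-ratio edge rejection, and
# orientation assignment from the gradient-direction histogram.

#' Locate raw extrema in the DoG stack
#'
#' Scans every interior pixel of every searchable DoG layer (the first and
#' last layer of each octave only serve as neighbors) for strict maxima or
#' minima over the 26-neighborhood (3 x 3 x 3 minus the center). Candidates
#' whose |D| falls below half the contrast threshold are dropped early; the
#' definitive contrast gate runs on the refined response.
#'
#' @param space A `scale_space` with the DoG filled (see [build_dog()]).
#' @return A tibble with columns `octave`, `layer`, `row`, `col`, `value`
#'   (octave-local integer grid coordinates and the raw DoG value).
#' @export
detect_extrema <- function(space) {
  stopifnot(inherits(space, "scale_space"))
  if (is.null(space$octaves[[1]]$dog)) {
    abort("DoG stack not built; call build_dog() first",
          class = "echotrack_error")
  }
  pre <- 0.5 * space$cfg$contrast_threshold
  out <- list()
  for (o in seq_along(space$octaves)) {
    dog <- space$octaves[[o]]$dog
    nd <- length(dog)
    h <- nrow(dog[[1]]); w <- ncol(dog[[1]])
    if (nd < 3 || h < 3 || w < 3) next
    ri <- 2:(h - 1); ci <- 2:(w - 1)
    for (l in 2:(nd - 1)) {
      ctr <- dog[[l]][ri, ci]
      alive <- abs(ctr) > pre
      if (!any(alive)) next
      is_mx <- alive; is_mn <- alive
      for (dz in -1:1) {
        lay <- dog[[l + dz]]
        for (dr in -1:1) for (dc in -1:1) {
          if (dz == 0 && dr == 0 && dc == 0) next
          nb <- lay[ri + dr, ci + dc]
          is_mx <- is_mx & (ctr > nb)
          is_mn <- is_mn & (ctr < nb)
          if (!any(is_mx) && !any(is_mn)) break
        }
      }
      hit <- which(is_mx | is_mn, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        out[[length(out) + 1]] <- tibble(
          octave = o, layer = l,
          row = hit[, 1] + 1L, col = hit[, 2] + 1L,
          value = ctr[hit]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(octave = integer(), layer = integer(), row = integer(),
                  col = integer(), value = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Refine an extremum to subpixel accuracy
#'
#' Fits the local quadratic model of the DoG around the candidate and solves
#' `xhat = -H^-1 g` (gradient and Hessian by central finite differences over
#' row, column, and layer). When any component of `xhat` exceeds 0.5 the
#' candidate is re-centered on the neighboring grid point and re-solved, up
#' to `max_moves` times. The refined response is
#' `D(xhat) = D + (1/2) g . xhat`.
#'
#' @param space A `scale_space` with DoG filled.
#' @param octave,layer,row,col Integer candidate location (octave-local).
#' @param max_moves Maximum number of grid re-centerings before rejection.
#' @return A list: `ok` (logical) plus, on success, octave-local refined
#'   coordinates (`row_oct`, `col_oct`, `layer_ref`), base-image coordinates
#'   (`row`, `col`), scales (`sigma_oct`, `sigma`), `response`, and `offset`
#'   (the final `xhat`); on failure, `reason` one of `"singular_hessian"`,
#'   `"out_of_bounds"`, `"no_convergence"`.
#' @export
refine_keypoint <- function(space, octave, layer, row, col, max_moves = 5L) {
  stopifnot(inherits(space, "scale_space"))
  oct <- space$octaves[[octave]]
  dog <- oct$dog
  nd <- length(dog)
  h <- nrow(dog[[1]]); w <- ncol(dog[[1]])
  r <- as.integer(row); c_ <- as.integer(col); l <- as.integer(layer)
  reject <- function(reason) list(ok = FALSE, reason = reason)
  if (l < 2 || l > nd - 1 || r < 2 || r > h - 1 || c_ < 2 || c_ > w - 1) {
    return(reject("out_of_bounds"))
  }
  for (move in seq_len(max_moves + 1L)) {
    d0 <- dog[[l]][r, c_]
    g <- 0.5 * c(dog[[l]][r + 1, c_] - dog[[l]][r - 1, c_],
                 dog[[l]][r, c_ + 1] - dog[[l]][r, c_ - 1],
                 dog[[l + 1]][r, c_] - dog[[l - 1]][r, c_])
    drr <- dog[[l]][r + 1, c_] - 2 * d0 + dog[[l]][r - 1, c_]
    dcc <- dog[[l]][r, c_ + 1] - 2 * d0 + dog[[l]][r, c_ - 1]
    dll <- dog[[l + 1]][r, c_] - 2 * d0 + dog[[l - 1]][r, c_]
    drc <- (dog[[l]][r + 1, c_ + 1] - dog[[l]][r + 1, c_ - 1] -
            dog[[l]][r - 1, c_ + 1] + dog[[l]][r - 1, c_ - 1]) / 4
    drl <- (dog[[l + 1]][r + 1, c_] - dog[[l + 1]][r - 1, c_] -
            dog[[l - 1]][r + 1, c_] + dog[[l - 1]][r - 1, c_]) / 4
    dcl <- (dog[[l + 1]][r, c_ + 1] - dog[[l + 1]][r, c_ - 1] -
            dog[[l - 1]][r, c_ + 1] + dog[[l - 1]][r, c_ - 1]) / 4
    H <- matrix(c(drr, drc, drl,
                  drc, dcc, dcl,
                  drl, dcl, dll), 3, 3)
    if (!is.finite(det(H)) || abs(det(H)) < 1e-12) {
      return(reject("singular_hessian"))
    }
    xhat <- as.numeric(solve(H, -g))
    if (all(abs(xhat) <= 0.5)) {
      cfg <- space$cfg
      response <- d0 + 0.5 * sum(g * xhat)
      layer_ref <- l + xhat[3]
      sigma_oct <- cfg$sigma0 * cfg$k^(layer_ref - 1)
      step <- oct$step
      return(list(
        ok = TRUE,
        row_oct = r + xhat[1], col_oct = c_ + xhat[2], layer_ref = layer_ref,
        layer_int = l, row_int = r, col_int = c_,
        row = (r + xhat[1] - 1) * step + 1,
        col = (c_ + xhat[2] - 1) * step + 1,
        sigma_oct = sigma_oct, sigma = sigma_oct * step,
        response = response, offset = xhat
      ))
    }
    if (move > max_moves) return(reject("no_convergence"))
    r <- r + sign(xhat[1]) * (abs(xhat[1]) > 0.5)
    c_ <- c_ + sign(xhat[2]) * (abs(xhat[2]) > 0.5)
    l <- l + sign(xhat[3]) * (abs(xhat[3]) > 0.5)
    if (l < 2 || l > nd - 1 || r < 2 || r > h - 1 || c_ < 2 || c_ > w - 1) {
      return(reject("out_of_bounds"))
    }
  }
  reject("no_convergence")
}

#' Contrast gate on the refined DoG response
#'
#' A keypoint is retained when its refined response reaches the threshold
#' (inclusive): `|D(xhat)| >= threshold` by default, or the signed response
#' when `use_abs = FALSE` (the literal one-sided reading that keeps only
#' bright blobs).
#'
#' @param response Refined response(s) `D(xhat)`.
#' @param threshold Contrast threshold (default 0.03).
#' @param use_abs Test `|D|` (default) rather than signed `D`.
#' @return Logical vector: `TRUE` = keep.
#' @export
contrast_filter <- function(response, threshold = 0.03, use_abs = TRUE) {
  v <- if (use_abs) abs(response) else response
  v >= threshold
}

#' Curvature-ratio edge rejection
#'
#' Points on intensity edges have one large and one small principal curvature
#' of the DoG; such points localize poorly along the edge. With `H` the 2 x 2
#' spatial Hessian at the keypoint, the point is kept iff `det(H) > 0` and
#' `tr(H)^2 / det(H) < (r + 1)^2 / r` (strict), `r` = `ratio_threshold`.
#'
#' @param space A `scale_space` with DoG filled.
#' @param octave,layer,row,col Integer keypoint location (octave-local; the
#'   grid point the refinement converged on).
#' @param ratio_threshold Maximum allowed principal-curvature ratio `r`.
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
edge_filter <- function(space, octave, layer, row, col, ratio_threshold = 10) {
  dog <- space$octaves[[octave]]$dog
  d <- dog[[layer]]
  r <- as.integer(row); c_ <- as.integer(col)
  if (r < 2 || r > nrow(d) - 1 || c_ < 2 || c_ > ncol(d) - 1) return(FALSE)
  d0 <- d[r, c_]
  drr <- d[r + 1, c_] - 2 * d0 + d[r - 1, c_]
  dcc <- d[r, c_ + 1] - 2 * d0 + d[r, c_ - 1]
  drc <- (d[r + 1, c_ + 1] - d[r + 1, c_ - 1] -
          d[r - 1, c_ + 1] + d[r - 1, c_ - 1]) / 4
  det_h <- drr * dcc - drc^2
  if (!is.finite(det_h) || det_h <= 0) return(FALSE)
  tr_h <- drr + dcc
  rt <- ratio_threshold
  (tr_h^2 / det_h) < ((rt + 1)^2 / rt)
}

# Central-difference gradients of one Gaussian layer. Border pixels get zero
# gradient (they are never sampled: windows are clipped to [2, n-1]).
layer_gradients <- function(layer_img) {
  h <- nrow(layer_img); w <- ncol(layer_img)
  grow <- matrix(0, h, w); gcol <- matrix(0, h, w)
  grow[2:(h - 1), ] <- layer_img[3:h, ] - layer_img[1:(h - 2), ]
  gcol[, 2:(w - 1)] <- layer_img[, 3:w] - layer_img[, 1:(w - 2)]
  list(grow = grow, gcol = gcol)
}

#' Assign gradient orientations to a keypoint
#'
#' Accumulates a 36-bin histogram of gradient directions
#' `theta = atan2(L(r+1, c) - L(r-1, c), L(r, c+1) - L(r, c-1))` weighted by
#' gradient magnitude `m` and a Gaussian of width `1.5 * sigma` over a
#' circular window of radius `3 * 1.5 * sigma` (octave-local pixels). The
#' peak bin gives the orientation, refined by parabolic interpolation over
#' the three bins around it; every secondary peak reaching 80% of the
#' maximum yields an additional orientation.
#'
#' @param space A `scale_space`.
#' @param octave Octave index.
#' @param layer Gaussian layer index used for the gradients (typically the
#'   rounded refined layer).
#' @param row_oct,col_oct Octave-local (possibly fractional) position.
#' @param sigma_oct Octave-relative scale of the keypoint.
#' @param grads Optional precomputed [layer_gradients()] of that layer.
#' @return Numeric vector of orientations in radians in `[0, 2 pi)`, primary
#'   peak first. All-zero gradients give `0` with a warning.
#' @export
assign_orientation <- function(space, octave, layer, row_oct, col_oct,
                               sigma_oct, grads = NULL) {
  oct <- space$octaves[[octave]]
  layer <- min(max(as.integer(layer), 1L), length(oct$gauss))
  img <- oct$gauss[[layer]]
  if (is.null(grads)) grads <- layer_gradients(img)
  h <- nrow(img); w <- ncol(img)
  sig_w <- 1.5 * sigma_oct
  radius <- max(1L, round(3 * sig_w))
  r0 <- round(row_oct); c0 <- round(col_oct)
  dr <- rep(seq(-radius, radius), times = 2 * radius + 1)
  dc <- rep(seq(-radius, radius), each = 2 * radius + 1)
  rr <- r0 + dr; cc <- c0 + dc
  keep <- dr^2 + dc^2 <= radius^2 &
    rr >= 2 & rr <= h - 1 & cc >= 2 & cc <= w - 1
  dr <- dr[keep]; dc <- dc[keep]; rr <- rr[keep]; cc <- cc[keep]
  if (length(rr) == 0) {
    warn("orientation window has no valid samples; orientation set to 0")
    return(0)
  }
  ij <- cbind(rr, cc)
  grow <- grads$grow[ij]; gcol <- grads$gcol[ij]
  m <- sqrt(grow^2 + gcol^2)
  if (max(m) <= 1e-12) {
    warn("all gradients zero in orientation window; orientation set to 0")
    return(0)
  }
  wgt <- exp(-(dr^2 + dc^2) / (2 * sig_w^2)) * m
  theta <- atan2(grow, gcol) %% (2 * pi)
  bin <- pmin(floor(theta / (2 * pi / 36)) + 1L, 36L)
  hist <- numeric(36)
  sums <- rowsum(wgt, bin)
  hist[as.integer(rownames(sums))] <- sums[, 1]
  peak <- max(hist)
  lft <- hist[c(36, 1:35)]; rgt <- hist[c(2:36, 1)]
  is_peak <- hist >= lft & hist >= rgt & hist >= 0.8 * peak & hist > 0
  bins <- which(is_peak)
  bins <- bins[order(hist[bins], decreasing = TRUE)]
  vapply(bins, function(b) {
    hl <- hist[if (b == 1) 36 else b - 1]
    hc <- hist[b]
    hr <- hist[if (b == 36) 1 else b + 1]
    den <- hl - 2 * hc + hr
    delta <- if (abs(den) < 1e-12) 0 else 0.5 * (hl - hr) / den
    (((b - 1) + 0.5 + delta) * 2 * pi / 36) %% (2 * pi)
  }, numeric(1))
}

#' Detect oriented keypoints in a frame
#'
#' Runs the full detector: scale space, DoG, 26-neighborhood extrema,
#' subpixel refinement, contrast gate, edge rejection, and orientation
#' assignment (one row per orientation when a keypoint has secondary peaks).
#'
#' @param frame Numeric matrix in \[0, 1\].
#' @param cfg A [scale_space_config()].
#' @param space Optionally a prebuilt `scale_space` of `frame` (with or
#'   without DoG); avoids rebuilding when the caller also needs it.
#' @return A tibble with one row per oriented keypoint: `id`, `row`, `col`
#'   (subpixel, base-image scale), `sigma`, `response`, `orientation`, and
#'   the octave-local fields `octave`, `layer`, `row_oct`, `col_oct`,
#'   `sigma_oct` used by the descriptor.
#' @export
detect_keypoints <- function(frame, cfg = scale_space_config(), space = NULL) {
  if (is.null(space)) {
    space <- build_scale_space(frame, cfg)
  } else {
    cfg <- space$cfg
  }
  if (is.null(space$octaves[[1]]$dog)) space <- build_dog(space)
  ext <- detect_extrema(space)
  empty <- tibble(id = integer(), row = numeric(), col = numeric(),
                  sigma = numeric(), response = numeric(),
                  orientation = numeric(), octave = integer(),
                  layer = integer(), row_oct = numeric(),
                  col_oct = numeric(), sigma_oct = numeric())
  if (nrow(ext) == 0) return(empty)
  grad_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(ext))
  for (i in seq_len(nrow(ext))) {
    rf <- refine_keypoint(space, ext$octave[i], ext$layer[i],
                          ext$row[i], ext$col[i])
    if (!isTRUE(rf$ok)) next
    if (!contrast_filter(rf$response, cfg$contrast_threshold,
                         use_abs = cfg$abs_response)) next
    if (!edge_filter(space, ext$octave[i], rf$layer_int, rf$row_int,
                     rf$col_int, cfg$edge_ratio)) next
    glayer <- min(max(round(rf$layer_ref), 1L),
                  length(space$octaves[[ext$octave[i]]]$gauss))
    key <- sprintf("%d_%d", ext$octave[i], glayer)
    if (is.null(grad_cache[[key]])) {
      grad_cache[[key]] <-
        layer_gradients(space$octaves[[ext$octave[i]]]$gauss[[glayer]])
    }
    ors <- suppressWarnings(
      assign_orientation(space, ext$octave[i], glayer, rf$row_oct,
                         rf$col_oct, rf$sigma_oct,
                         grads = grad_cache[[key]])
    )
    rows[[i]] <- tibble(
      row = rf$row, col = rf$col, sigma = rf$sigma, response = rf$response,
      orientation = ors, octave = ext$octave[i], layer = glayer,
      row_oct = rf$row_oct, col_oct = rf$col_oct, sigma_oct = rf$sigma_oct
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  kps <- dplyr::bind_rows(rows)
  kps <- dplyr::distinct(kps,
                         dplyr::across(c("octave", "layer")),
                         r2 = round(.data$row_oct * 2),
                         c2 = round(.data$col_oct * 2),
                         o36 = round(.data$orientation * 18 / pi),
                         .keep_all = TRUE)
  kps$r2 <- NULL; kps$c2 <- NULL; kps$o36 <- NULL
  kps <- dplyr::arrange(kps, dplyr::desc(abs(.data$response)))
  kps$id <- seq_len(nrow(kps))
  dplyr::relocate(kps, "id")
}
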