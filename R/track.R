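# Tolerance-gated speckle tracking over a frame sequence.
#
# Each consecutive frame pair is despeckled, keypoints are extracted and
# described, descriptor sets are matched with the ratio test, and every
# tracked point adopts the accepted match nearest its current position,
# optionally polished by pyramid LK flow. A per-frame displacement beyond
# the tolerance marks the point lost for that frame, recorded with the
# sentinel coordinates (0, 0); by default the point may be re-acquired near
# its last known position in later frames.

#' Configure the tracking pipeline
#'
#' @param tolerance Per-frame displacement gate in pixels, in \[1, 20\].
#' @param refine_with_lk Polish each matched displacement with
#'   [pyramid_flow()].
#' @param reacquire Keep searching near the last known position after a lost
#'   frame (default `TRUE`); `FALSE` makes a loss permanent.
#' @param denoise Apply [mean_filter()] to each frame before extraction.
#' @param filter A [mean_filter_spec()].
#' @param scale A [scale_space_config()].
#' @param descriptor A [descriptor_config()].
#' @param match A [match_config()].
#' @param lk An [lk_config()].
#' @return An object of class `track_config`.
#' @export
track_config <- function(tolerance = 20, refine_with_lk = TRUE,
                         reacquire = TRUE, denoise = TRUE,
                         filter = mean_filter_spec(),
                         scale = scale_space_config(),
                         descriptor = descriptor_config(),
                         match = match_config(),
                         lk = lk_config()) {
  if (!is.numeric(tolerance) || tolerance < 1 || tolerance > 20) {
    abort("`tolerance` must lie in [1, 20] pixels",
          class = "echotrack_config_error")
  }
  structure(list(tolerance = tolerance, refine_with_lk = refine_with_lk,
                 reacquire = reacquire, denoise = denoise, filter = filter,
                 scale = scale, descriptor = descriptor, match = match,
                 lk = lk),
            class = "track_config")
}

#' Tolerance gate on a frame-to-frame displacement
#'
#' Accepts the candidate when its Euclidean displacement from the previous
#' position is at most `tolerance` pixels (inclusive); otherwise the point is
#' lost for this frame and the sentinel (0, 0) is recorded.
#'
#' @param prev,candidate Positions `c(row, col)`.
#' @param tolerance Gate in pixels, in \[1, 20\].
#' @return List with `accept` (logical), `row`, `col` (candidate or sentinel)
#'   and `displacement`.
#' @export
tolerance_gate <- function(prev, candidate, tolerance = 20) {
  if (tolerance < 1 || tolerance > 20) {
    abort("`tolerance` must lie in [1, 20] pixels",
          class = "echotrack_config_error")
  }
  d <- disp_norm(candidate[1] - prev[1], candidate[2] - prev[2])
  if (is.finite(d) && d <= tolerance) {
    list(accept = TRUE, row = candidate[1], col = candidate[2],
         displacement = d)
  } else {
    list(accept = FALSE, row = 0, col = 0, displacement = d)
  }
}

as_frame_list <- function(frames) {
  if (inherits(frames, "echo_sequence")) frames$frames
  else if (is.list(frames)) frames
  else abort("`frames` must be a list of matrices or an echo_sequence",
             class = "echotrack_error")
}

#' Track seed points through a frame sequence
#'
#' @param frames List of grayscale matrices (or an `echo_sequence`).
#' @param seeds Data frame with columns `row`, `col` (frame-1 positions) and
#'   optionally `point_id`.
#' @param cfg A [track_config()].
#' @return An `echo_tracks` tibble with one row per point per frame:
#'   `point_id`, `frame`, `row`, `col`, `lost` (lost frames hold the
#'   sentinel 0, 0). Attributes: `summary` (per-frame feature/match/lost
#'   counts), `config`, `dim`.
#' @export
track_sequence <- function(frames, seeds, cfg = track_config()) {
  frames <- as_frame_list(frames)
  n_frames <- length(frames)
  if (n_frames < 2) abort("need at least 2 frames",
                          class = "echotrack_error")
  stopifnot(inherits(cfg, "track_config"))
  seeds <- as_tibble(seeds)
  if (is.null(seeds$point_id)) seeds$point_id <- seq_len(nrow(seeds))
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  if (any(seeds$row < 1 | seeds$row > h | seeds$col < 1 | seeds$col > w)) {
    abort("all seed points must lie inside frame 1",
          class = "echotrack_error")
  }
  np <- nrow(seeds)
  pos <- cbind(seeds$row, seeds$col)   # last known (anchor) positions
  active <- rep(TRUE, np)              # FALSE only when lost and !reacquire
  recs <- vector("list", n_frames)
  recs[[1]] <- tibble(point_id = seeds$point_id, frame = 1L,
                      row = seeds$row, col = seeds$col, lost = FALSE)
  summ <- vector("list", n_frames - 1L)
  prep <- function(fr) if (cfg$denoise) mean_filter(fr, cfg$filter) else fr
  for (t in seq_len(n_frames - 1L)) {
    f <- prep(frames[[t]]); g <- prep(frames[[t + 1L]])
    fa <- sift_features(f, cfg$scale, cfg$descriptor)
    fb <- sift_features(g, cfg$scale, cfg$descriptor)
    m <- if (nrow(fa) > 0 && nrow(fb) > 1) {
      match_images(fa, fb, cfg$match)
    } else {
      empty_matches()
    }
    new_row <- numeric(np); new_col <- numeric(np); lost <- rep(TRUE, np)
    for (i in seq_len(np)) {
      if (!active[i]) { new_row[i] <- 0; new_col[i] <- 0; next }
      anchor <- pos[i, ]
      cand <- NULL
      if (nrow(m) > 0) {
        dist_a <- disp_norm(m$row_a - anchor[1], m$col_a - anchor[2])
        best <- order(dist_a, m$r)[1]
        # the matched pair's own displacement seeds the point's motion
        b0 <- c(m$row_b[best] - m$row_a[best], m$col_b[best] - m$col_a[best])
        cand <- anchor + b0
      }
      if (is.null(cand)) { new_row[i] <- 0; new_col[i] <- 0; next }
      if (cfg$refine_with_lk) {
        est <- tryCatch(
          pyramid_flow(f, g, anchor, cfg$lk, b0 = b0),
          error = function(e) NULL
        )
        if (!is.null(est) && all(is.finite(est$b))) cand <- anchor + est$b
      }
      gate <- tolerance_gate(anchor, cand, cfg$tolerance)
      inside <- gate$accept && cand[1] >= 1 && cand[1] <= h &&
        cand[2] >= 1 && cand[2] <= w
      if (inside) {
        pos[i, ] <- cand
        new_row[i] <- cand[1]; new_col[i] <- cand[2]; lost[i] <- FALSE
      } else {
        new_row[i] <- 0; new_col[i] <- 0
        if (!cfg$reacquire) active[i] <- FALSE
      }
    }
    recs[[t + 1L]] <- tibble(point_id = seeds$point_id, frame = t + 1L,
                             row = new_row, col = new_col, lost = lost)
    summ[[t]] <- tibble(frame = t + 1L, features_prev = nrow(fa),
                        features_next = nrow(fb), matches = nrow(m),
                        lost = sum(lost))
  }
  out <- dplyr::bind_rows(recs)
  structure(out,
            class = c("echo_tracks", class(out)),
            summary = dplyr::bind_rows(summ),
            config = cfg, dim_frame = c(h, w))
}

#' Write trajectories to CSV
#'
#' Columns `point_id`, `frame`, `abscissa` (column coordinate), `ordinate`
#' (row coordinate), `lost`; lost frames emit the 0, 0 sentinel.
#'
#' @param trajs An `echo_tracks` tibble (or any data frame with `point_id`,
#'   `frame`, `row`, `col`, `lost`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_trajectories <- function(trajs, path) {
  if (nrow(trajs) == 0) abort("no trajectories to export",
                              class = "echotrack_error")
  df <- data.frame(point_id = trajs$point_id, frame = trajs$frame,
                   abscissa = trajs$col, ordinate = trajs$row,
                   lost = trajs$lost)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(sprintf("cannot write '%s'", path),
                 class = "echotrack_io_error")
  invisible(path)
}

#' Read trajectories written by [export_trajectories()]
#'
#' @param path CSV file path.
#' @return An `echo_tracks`-shaped tibble (`point_id`, `frame`, `row`, `col`,
#'   `lost`).
#' @export
import_trajectories <- function(path) {
  df <- utils::read.csv(path)
  out <- tibble(point_id = df$point_id, frame = as.integer(df$frame),
                row = df$ordinate, col = df$abscissa,
                lost = as.logical(df$lost))
  structure(out, class = c("echo_tracks", class(out)))
}

#' Per-frame contraction (shrinkage) curve
#'
#' For each frame, the mean Euclidean distance of the surviving (non-lost)
#' tracked points from a reference, normalized by its frame-1 value. On a
#' contracting ventricle-like motion the series dips at peak systole; a
#' static sequence gives the constant 1.
#'
#' @param trajs An `echo_tracks` tibble.
#' @param reference `c(row, col)`, or `NULL` (default) to use the per-frame
#'   centroid of the surviving points.
#' @return A tibble with columns `frame` and `value` (`NA` for frames where
#'   every point is lost).
#' @export
contraction_curve <- function(trajs, reference = NULL) {
  if (nrow(trajs) == 0) abort("no trajectories", class = "echotrack_error")
  frames <- sort(unique(trajs$frame))
  vals <- vapply(frames, function(f) {
    d <- trajs[trajs$frame == f & !trajs$lost, , drop = FALSE]
    if (nrow(d) == 0) return(NA_real_)
    ref <- if (is.null(reference)) c(mean(d$row), mean(d$col)) else reference
    mean(disp_norm(d$row - ref[1], d$col - ref[2]))
  }, numeric(1))
  base <- vals[1]
  if (is.na(base) || base == 0) {
    # degenerate frame-1 reference (single point at the centroid): report raw
    return(tibble(frame = frames, value = vals))
  }
  tibble(frame = frames, value = vals / base)
}

#' @export
print.echo_tracks <- function(x, ...) {
  np <- length(unique(x$point_id)); nf <- length(unique(x$frame))
  cat(sprintf("<echo_tracks> %d point(s) over %d frame(s), %d lost record(s)\n",
              np, nf, sum(x$lost)))
  NextMethod()
}

#' Tidy an `echo_tracks` object
#'
#' @param x An `echo_tracks` tibble.
#' @param ... Unused.
#' @return A plain tibble with `point_id`, `frame`, `row`, `col`, `lost`.
#' @importFrom generics tidy
#' @export
#' @method tidy echo_tracks
tidy.echo_tracks <- function(x, ...) {
  tibble(point_id = x$point_id, frame = x$frame, row = x$row, col = x$col,
         lost = x$lost)
}

#' One-row summary of a tracking run
#'
#' @param x An `echo_tracks` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `n_points`, `n_frames`, `lost_records`,
#'   `full_trajectories` (points never lost), `mean_step_px` (mean per-frame
#'   displacement over surviving consecutive records).
#' @importFrom generics glance
#' @export
#' @method glance echo_tracks
glance.echo_tracks <- function(x, ...) {
  np <- length(unique(x$point_id)); nf <- length(unique(x$frame))
  full <- sum(vapply(split(x$lost, x$point_id),
                     function(l) !any(l), logical(1)))
  steps <- unlist(lapply(split(seq_len(nrow(x)), x$point_id), function(ii) {
    d <- x[ii, ][order(x$frame[ii]), ]
    keep <- !d$lost[-1] & !d$lost[-nrow(d)]
    disp_norm(diff(d$row), diff(d$col))[keep]
  }))
  tibble(n_points = np, n_frames = nf, lost_records = sum(x$lost),
         full_trajectories = full,
         mean_step_px = if (length(steps)) mean(steps) else NA_real_)
}

#' @export
generics::tidy

#' @export
generics::glance
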