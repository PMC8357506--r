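# ggplot2 visualizations for frames, keypoints, matches, and trajectories.

frame_df <- function(frame) {
  tibble(row = rep(seq_len(nrow(frame)), times = ncol(frame)),
         col = rep(seq_len(ncol(frame)), each = nrow(frame)),
         intensity = as.vector(frame))
}

gg_frame <- function(frame) {
  ggplot2::ggplot(frame_df(frame),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot detected keypoints over a frame
#'
#' Circles are drawn at keypoint positions with radius proportional to scale
#' and a tick at the assigned orientation.
#'
#' @param frame Numeric matrix.
#' @param keypoints Tibble from [detect_keypoints()].
#' @return A ggplot object.
#' @export
plot_keypoints <- function(frame, keypoints) {
  p <- gg_frame(frame)
  if (nrow(keypoints) == 0) return(p)
  p +
    ggplot2::geom_point(data = keypoints,
                        ggplot2::aes(x = .data$col, y = .data$row,
                                     size = .data$sigma),
                        inherit.aes = FALSE, colour = "red", shape = 1) +
    ggplot2::geom_segment(
      data = keypoints,
      ggplot2::aes(x = .data$col, y = .data$row,
                   xend = .data$col + 2 * .data$sigma * cos(.data$orientation),
                   yend = .data$row + 2 * .data$sigma * sin(.data$orientation)),
      inherit.aes = FALSE, colour = "red", linewidth = 0.3) +
    ggplot2::scale_size_identity()
}

#' Plot accepted matches between two frames side by side
#'
#' @param frame_a,frame_b Numeric matrices.
#' @param matches Tibble from [match_images()] (needs the coordinate
#'   columns).
#' @return A ggplot object.
#' @export
plot_matches <- function(frame_a, frame_b, matches) {
  gap <- 8
  w <- ncol(frame_a)
  both <- dplyr::bind_rows(
    frame_df(frame_a),
    dplyr::mutate(frame_df(frame_b), col = .data$col + w + gap)
  )
  p <- ggplot2::ggplot(both, ggplot2::aes(x = .data$col, y = .data$row,
                                          fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (nrow(matches) == 0) return(p)
  p + ggplot2::geom_segment(
    data = matches,
    ggplot2::aes(x = .data$col_a, y = .data$row_a,
                 xend = .data$col_b + w + gap, yend = .data$row_b),
    inherit.aes = FALSE, colour = "red", alpha = 0.7, linewidth = 0.3)
}

#' Plot tracked trajectories
#'
#' One path per point over the frame sequence; lost records are dropped from
#' the paths.
#'
#' @param object An `echo_tracks` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot echo_tracks
autoplot.echo_tracks <- function(object, ...) {
  d <- object[!object$lost, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  group = .data$point_id,
                                  colour = factor(.data$point_id))) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", colour = "point") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a contraction curve
#'
#' @param curve Tibble from [contraction_curve()].
#' @return A ggplot object.
#' @export
plot_contraction <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "frame", y = "normalized mean distance") +
    ggplot2::theme_minimal()
}
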