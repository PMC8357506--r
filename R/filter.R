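# Despeckling by linear mean filtering.
#
# Echocardiographic frames carry isolated bright/dark noise pixels (salt and
# pepper, impulse) on top of the speckle texture. A weighted neighborhood
# average g(x, y) = sum w(i, j) f(x + i, y + j) over an m x n mask suppresses
# them before feature extraction; with uniform weights each output pixel is
# the plain mean of its D = m * n neighbors.

#' Specify a linear mean filter mask
#'
#' @param rows,cols Odd mask dimensions in pixels.
#' @param weights Optional numeric `rows x cols` matrix of mask weights;
#'   normalized to sum to 1. Default is the uniform mask (every weight
#'   `1 / (rows * cols)`).
#' @return An object of class `mean_filter_spec`.
#' @export
mean_filter_spec <- function(rows = 3L, cols = rows, weights = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1 || cols < 1 ||
      rows %% 2L == 0L || cols %% 2L == 0L) {
    abort("mask dimensions must be odd and >= 1",
          class = "echotrack_config_error")
  }
  if (is.null(weights)) {
    weights <- matrix(1 / (rows * cols), rows, cols)
  } else {
    if (!is.matrix(weights) || !all(dim(weights) == c(rows, cols))) {
      abort("`weights` must be a rows x cols matrix",
            class = "echotrack_config_error")
    }
    s <- sum(weights)
    if (s <= 0) abort("mask weights must sum to a positive value",
                      class = "echotrack_config_error")
    weights <- weights / s
  }
  structure(list(rows = rows, cols = cols, weights = weights),
            class = "mean_filter_spec")
}

#' Despeckle a frame with a linear mean filter
#'
#' Each output pixel is the weighted average of its `rows x cols`
#' neighborhood; borders are handled by edge replication so the output has
#' the same size as the input.
#'
#' @param frame Numeric matrix.
#' @param spec A [mean_filter_spec()]; default 3 x 3 uniform.
#' @return Filtered frame, same dimensions.
#' @export
mean_filter <- function(frame, spec = mean_filter_spec()) {
  assert_frame(frame)
  stopifnot(inherits(spec, "mean_filter_spec"))
  if (spec$rows >= nrow(frame) || spec$cols >= ncol(frame)) {
    abort("filter mask must be smaller than the frame",
          class = "echotrack_config_error")
  }
  conv2_replicate(frame, spec$weights)
}

#' Convert an RGB array to grayscale
#'
#' Uses the Rec. 601 luma weights (0.299, 0.587, 0.114). Matrices pass
#' through unchanged.
#'
#' @param img A numeric matrix (returned as is) or an `h x w x 3` (or
#'   `h x w x 4`, alpha ignored) array.
#' @return A numeric matrix.
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3 && dim(img)[3] >= 3) {
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  }
  if (length(dim(img)) == 3 && dim(img)[3] == 1) return(img[, , 1])
  abort("cannot interpret image array as grayscale or RGB",
        class = "echotrack_error")
}
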