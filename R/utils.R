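# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Validate that `x` is a numeric matrix usable as a grayscale frame.
assert_frame <- function(x, arg = "frame") {
  if (!is.matrix(x) || !is.numeric(x) || any(dim(x) < 1)) {
    abort(sprintf("`%s` must be a non-empty numeric matrix", arg),
          class = "echotrack_error")
  }
  invisible(x)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# 2-D convolution with edge replication, output same size as input.
# `kernel` must have odd dimensions.
conv2_replicate <- function(frame, kernel) {
  EBImage::filter2(frame, kernel, boundary = "replicate")
}

# Bilinear sampling of `frame` at (possibly fractional) positions, with
# coordinates clamped to the frame so out-of-range samples replicate edges.
# `rows`, `cols` are equal-length numeric vectors (1-based).
bilinear_sample <- function(frame, rows, cols) {
  h <- nrow(frame); w <- ncol(frame)
  rows <- pmin(pmax(rows, 1), h)
  cols <- pmin(pmax(cols, 1), w)
  r0 <- pmin(floor(rows), h - 1L); c0 <- pmin(floor(cols), w - 1L)
  if (h == 1L) r0 <- rep(1L, length(rows))
  if (w == 1L) c0 <- rep(1L, length(cols))
  fr <- rows - r0; fc <- cols - c0
  r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)
  idx <- function(r, c) frame[cbind(r, c)]
  idx(r0, c0) * (1 - fr) * (1 - fc) +
    idx(r1, c0) * fr * (1 - fc) +
    idx(r0, c1) * (1 - fr) * fc +
    idx(r1, c1) * fr * fc
}

# Euclidean norm of a displacement (drow, dcol).
disp_norm <- function(drow, dcol) sqrt(drow^2 + dcol^2)
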