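# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Standard study phantom: fine speckle texture, full display range.
std_spec <- function(n = 128, seed = 7, blur = 1.2, ...) {
  phantom_spec(n, n, speckle_density = 0.15, blur_sigma = blur,
               seed = seed, ...)
}

std_frame <- function(n = 128, seed = 7, blur = 1.2) {
  cached(sprintf("frame_%d_%d_%g", n, seed, blur),
         make_speckle_frame(std_spec(n, seed, blur)))
}

std_features <- function(n = 128, seed = 7, blur = 1.2) {
  cached(sprintf("feats_%d_%d_%g", n, seed, blur),
         sift_features(std_frame(n, seed, blur)))
}

# Exact integer shift by reindexing with edge replication (no interpolation).
shift_int <- function(frame, dr, dc) {
  h <- nrow(frame); w <- ncol(frame)
  ri <- pmin(pmax(seq_len(h) - dr, 1), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1), w)
  frame[ri, ci]
}

# Linear ramp along rows, slope `slope` per pixel.
row_ramp <- function(n, slope = 1 / 64) {
  matrix(rep(seq_len(n), times = n), n, n) * slope
}

# Minimal hand-built scale_space carrying analytic DoG layers (one octave),
# for exercising refine_keypoint / edge_filter on known functions.
fake_space <- function(dog_layers, step = 1, cfg = scale_space_config()) {
  structure(list(
    octaves = list(list(dog = dog_layers,
                        gauss = dog_layers,   # unused by refinement
                        sigma_rel = cfg$sigma0 * cfg$k^(seq_along(dog_layers) - 1),
                        step = step)),
    cfg = cfg, dim = dim(dog_layers[[1]])
  ), class = "scale_space")
}

# Quadratic DoG patch with vertex at (r0, c0, l0) and peak value `peak`:
# D = peak - a * ((r - r0)^2 + (c - c0)^2 + (l - l0)^2)
quadratic_dog <- function(n = 11, nlayers = 3, r0, c0, l0, peak = 0.1,
                          a = 0.005) {
  lapply(seq_len(nlayers), function(l) {
    outer(seq_len(n), seq_len(n), function(r, c) {
      peak - a * ((r - r0)^2 + (c - c0)^2 + (l - l0)^2)
    })
  })
}
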