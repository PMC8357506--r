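test_that("extrema detection finds blobs and nothing on flat frames", {
  flat <- build_dog(build_scale_space(matrix(0.3, 64, 64)))
  expect_equal(nrow(detect_extrema(flat)), 0)
  # one isolated bright blob in a flat field
  blob <- gaussian_kernel_2d(2.5, radius = 12)
  f <- matrix(0, 64, 64)
  f[20:44, 20:44] <- blob / max(blob)
  sp <- build_dog(build_scale_space(f))
  ext <- detect_extrema(sp)
  expect_gt(nrow(ext), 0)
  base_row <- (ext$row - 1) * 2^(ext$octave - 1) + 1
  base_col <- (ext$col - 1) * 2^(ext$octave - 1) + 1
  expect_lt(min(sqrt((base_row - 32)^2 + (base_col - 32)^2)), 2)
  # negated image: same locations, max/min roles swapped
  sp_neg <- build_dog(build_scale_space(1 - f))
  ext_neg <- detect_extrema(sp_neg)
  key <- function(e) paste(e$octave, e$layer, e$row, e$col)
  expect_setequal(key(ext), key(ext_neg))
  expect_equal(ext$value[order(key(ext))],
               -ext_neg$value[order(key(ext_neg))], tolerance = 1e-12)
})

test_that("refinement recovers analytic quadratic vertices", {
  dog <- quadratic_dog(11, 3, r0 = 6.3, c0 = 5.8, l0 = 2)
  sp <- fake_space(dog)
  rf <- refine_keypoint(sp, 1, 2, 6, 6)
  expect_true(rf$ok)
  expect_equal(rf$offset[1], 0.3, tolerance = 1e-6)
  expect_equal(rf$offset[2], -0.2, tolerance = 1e-6)
  expect_equal(rf$offset[3], 0, tolerance = 1e-6)
  expect_equal(rf$response, 0.1, tolerance = 1e-9)  # peak value at the vertex
  # vertex exactly on the grid
  dog0 <- quadratic_dog(11, 3, r0 = 6, c0 = 6, l0 = 2)
  rf0 <- refine_keypoint(fake_space(dog0), 1, 2, 6, 6)
  expect_true(rf0$ok)
  expect_equal(max(abs(rf0$offset)), 0, tolerance = 1e-12)
  # flat patch: singular Hessian is rejected
  flat <- lapply(1:3, function(i) matrix(0.05, 11, 11))
  rff <- refine_keypoint(fake_space(flat), 1, 2, 6, 6)
  expect_false(rff$ok)
  expect_equal(rff$reason, "singular_hessian")
})

test_that("refinement re-centers onto the neighboring grid point", {
  # vertex 0.8 px away: first solve exceeds 0.5, so the candidate must move
  dog <- quadratic_dog(11, 3, r0 = 6.8, c0 = 6, l0 = 2)
  rf <- refine_keypoint(fake_space(dog), 1, 2, 6, 6)
  expect_true(rf$ok)
  expect_equal(rf$row_oct, 6.8, tolerance = 1e-6)
  expect_lte(max(abs(rf$offset)), 0.5)
})

test_that("contrast gate keeps |D| >= 0.03 inclusively", {
  expect_true(contrast_filter(0.05))
  expect_false(contrast_filter(0.01))
  expect_true(contrast_filter(0.03))          # boundary is inclusive
  expect_true(contrast_filter(-0.05))         # DoG minima kept by default
  expect_false(contrast_filter(-0.05, use_abs = FALSE))  # literal reading
})

test_that("edge rejection discards ridges and the exact boundary ratio", {
  # isotropic bowl: tr^2/det = 4 < 12.1
  iso <- quadratic_dog(11, 3, r0 = 6, c0 = 6, l0 = 2)
  expect_true(edge_filter(fake_space(iso), 1, 2, 6, 6))
  # ideal straight ridge: zero curvature along the ridge, det <= 0
  ridge <- lapply(1:3, function(l) {
    outer(seq_len(11), seq_len(11), function(r, c) 0.1 - 0.01 * (r - 6)^2)
  })
  expect_false(edge_filter(fake_space(ridge), 1, 2, 6, 6))
  # curvature ratio exactly 10: tr^2/det = 12.1 fails the strict inequality
  # (integer curvatures -20 and -2 keep both sides of the comparison exact)
  aniso <- lapply(1:3, function(l) {
    outer(seq_len(11), seq_len(11),
          function(r, c) 0.5 - 10 * (r - 6)^2 - 1 * (c - 6)^2)
  })
  expect_false(edge_filter(fake_space(aniso), 1, 2, 6, 6, ratio_threshold = 10))
  expect_true(edge_filter(fake_space(aniso), 1, 2, 6, 6, ratio_threshold = 10.01))
})

test_that("orientation follows the gradient direction formulas", {
  n <- 33
  cfg <- scale_space_config()
  # intensity increasing along columns: gradient angle 0
  colp <- outer(seq_len(n), seq_len(n), function(r, c) c / n)
  spc <- fake_space(list(colp, colp, colp))
  th <- suppressWarnings(assign_orientation(spc, 1, 2, 17, 17, 1.6))
  expect_lt(min(abs(c(th[1], th[1] - 2 * pi))), 0.1)
  # increasing along rows: angle pi/2
  rowp <- outer(seq_len(n), seq_len(n), function(r, c) r / n)
  spr <- fake_space(list(rowp, rowp, rowp))
  thr <- suppressWarnings(assign_orientation(spr, 1, 2, 17, 17, 1.6))
  expect_lt(abs(thr[1] - pi / 2), 0.1)
  # equal finite differences: angle pi/4, magnitude g * sqrt(2)
  diag_ <- outer(seq_len(n), seq_len(n), function(r, c) (r + c) / n)
  g <- echotrack:::layer_gradients(diag_)
  expect_equal(g$grow[17, 17], g$gcol[17, 17])
  expect_equal(sqrt(g$grow[17, 17]^2 + g$gcol[17, 17]^2),
               sqrt(2) * g$grow[17, 17], tolerance = 1e-12)
  thd <- suppressWarnings(assign_orientation(fake_space(list(diag_, diag_, diag_)),
                                             1, 2, 17, 17, 1.6))
  expect_lt(abs(thd[1] - pi / 4), 0.1)
  # all-zero gradients: orientation 0 with a warning
  flat <- matrix(0.2, n, n)
  expect_warning(
    th0 <- assign_orientation(fake_space(list(flat, flat, flat)),
                              1, 2, 17, 17, 1.6),
    "zero")
  expect_equal(th0, 0)
})

test_that("detector is equivariant to integer translation", {
  f <- std_frame(160, seed = 7)
  # a multiple of 2^(octaves - 1) so every octave sees an integer shift and
  # downsampled grids remain exact translates
  dr <- 8; dc <- 8
  f2 <- shift_int(f, dr, dc)
  k1 <- detect_keypoints(f)
  k2 <- detect_keypoints(f2)
  marg <- 48
  interior <- k1$row > marg & k1$row < 160 - marg &
    k1$col > marg & k1$col < 160 - marg
  expect_gt(sum(interior), 5)
  for (i in which(interior)) {
    d <- sqrt((k2$row - k1$row[i] - dr)^2 + (k2$col - k1$col[i] - dc)^2)
    expect_lt(min(d), 0.1)
  }
})

test_that("stored responses respect the contrast gate; lowering it only adds", {
  k3 <- std_features(128, seed = 7)
  expect_true(all(abs(k3$response) >= 0.03))
  f <- std_frame(128, seed = 7)
  k_lo <- detect_keypoints(f, scale_space_config(contrast_threshold = 0.02))
  k_hi <- detect_keypoints(f, scale_space_config(contrast_threshold = 0.03))
  expect_gte(nrow(k_lo), nrow(k_hi))
  for (i in seq_len(nrow(k_hi))) {
    d <- sqrt((k_lo$row - k_hi$row[i])^2 + (k_lo$col - k_hi$col[i])^2)
    expect_lt(min(d), 1e-6)
  }
})
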