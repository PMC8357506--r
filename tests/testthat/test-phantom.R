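test_that("speckle frames are deterministic, calibrated, and bounded", {
  spec <- phantom_spec(64, 64, speckle_density = 0.1, blur_sigma = 0, seed = 7)
  f1 <- make_speckle_frame(spec)
  f2 <- make_speckle_frame(spec)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0 & f1 <= 1))
  # binomial count oracle: nonzero pre-blur fraction ~ density
  expect_lt(abs(mean(f1 > 0) - 0.1), 0.02)
  # no scatterers at density zero
  f0 <- make_speckle_frame(phantom_spec(64, 64, speckle_density = 0,
                                        blur_sigma = 1, seed = 1))
  expect_true(all(f0 == 0))
  expect_error(phantom_spec(16, 64), class = "echotrack_config_error")
  expect_error(phantom_spec(64, 64, speckle_density = 1.2),
               class = "echotrack_config_error")
})

test_that("warp_frame is the identity on a zero field and exact on shifts", {
  f <- std_frame(64, seed = 2)
  zero <- list(drow = matrix(0, 64, 64), dcol = matrix(0, 64, 64))
  expect_identical(warp_frame(f, zero), f)
  # impulse moves by the (row, col) offset
  imp <- matrix(0, 32, 32); imp[16, 16] <- 1
  fld <- list(drow = matrix(2, 32, 32), dcol = matrix(0, 32, 32))
  out <- warp_frame(imp, fld)
  expect_equal(out[18, 16], 1)
  expect_equal(sum(out), 1)
  # analytic ramp oracle: 0.5 px shift offsets values by 0.5 * slope
  rmp <- row_ramp(32, slope = 0.01)
  half <- list(drow = matrix(0.5, 32, 32), dcol = matrix(0, 32, 32))
  wr <- warp_frame(rmp, half)
  expect_equal(wr[5:28, ], rmp[5:28, ] - 0.5 * 0.01, tolerance = 1e-12)
  bad <- list(drow = matrix(0, 16, 16), dcol = matrix(0, 16, 16))
  expect_error(warp_frame(f, bad), class = "echotrack_error")
})

test_that("noise kinds are calibrated and deterministic", {
  f <- matrix(0.5, 100, 100)
  expect_identical(add_noise(f, "gaussian", 0, seed = 1), f)
  sp <- add_noise(f, "salt_pepper", 0.05, seed = 3)
  expect_identical(sp, add_noise(f, "salt_pepper", 0.05, seed = 3))
  expect_lt(abs(mean(sp != 0.5) - 0.05), 0.01)
  expect_true(all(sp %in% c(0, 0.5, 1)))
  g <- add_noise(f, "gaussian", 0.1, seed = 4)
  expect_lt(abs(stats::sd(g - f) - 0.1), 0.01)
  expect_error(add_noise(f, "poisson", 0.1), "arg")
})

test_that("sequences accumulate motion with recoverable ground truth", {
  spec <- std_spec(64, seed = 3)
  sq <- make_sequence(spec, motion_model("translation", shift = c(1, 0)), 5)
  expect_length(sq$frames, 5)
  expect_equal(sq$fields[[5]]$drow[1, 1], 4)   # cumulative at t = 4
  expect_equal(sq$fields[[1]]$drow[20, 20], 0) # frame 0 field is zero
  # noise-free ground-truth consistency (translation: pull = forward field)
  pull <- motion_field(sq$motion, 3, 64, 64, type = "pull")
  expect_equal(mean(abs(warp_frame(sq$frames[[1]], pull) - sq$frames[[4]])), 0)
  # zero rotation leaves all frames equal
  sq0 <- make_sequence(spec, motion_model("rotation", degrees = 0), 3)
  expect_identical(sq0$frames[[1]], sq0$frames[[3]])
  # determinism with noise on
  spn <- std_spec(64, seed = 3, noise_kind = "gaussian", noise_level = 0.05)
  m <- motion_model("rotation", degrees = 2)
  expect_identical(make_sequence(spn, m, 3)$frames,
                   make_sequence(spn, m, 3)$frames)
  expect_error(make_sequence(spec, m, 1), class = "echotrack_config_error")
})

test_that("periodic radial motion completes its cycle and peaks mid-period", {
  m <- motion_model("periodic_radial", amplitude = 3, period = 20)
  f0 <- motion_field(m, 0, 64, 64)
  f20 <- motion_field(m, 20, 64, 64)
  expect_equal(f20$drow, f0$drow, tolerance = 1e-12)
  expect_equal(f20$dcol, f0$dcol, tolerance = 1e-12)
  # peak inward displacement at half period: `amplitude` px at the inscribed
  # circle radius
  pt <- data.frame(row = 32.5 + 32, col = 32.5)  # 32 px below center
  at10 <- motion_apply(m, 10, pt, 64, 64)
  expect_equal(32.5 + 32 - at10$row, 3, tolerance = 1e-9)
  # forward and pull fields are mutually consistent: warping by pull moves a
  # frame-0 impulse to its forward-mapped position
  expect_equal(motion_apply(m, 10, motion_apply(m, 0, pt, 64, 64), 64, 64),
               at10)
})

test_that("rotation fields agree with the analytic point map", {
  m <- motion_model("rotation", degrees = 30)
  gt <- motion_apply(m, 1, data.frame(row = 40, col = 20), 64, 64)
  fld <- motion_field(m, 1, 64, 64, type = "forward")
  expect_equal(40 + fld$drow[40, 20], gt$row, tolerance = 1e-9)
  expect_equal(20 + fld$dcol[40, 20], gt$col, tolerance = 1e-9)
  # norm preservation about the center
  ctr <- c((64 + 1) / 2, (64 + 1) / 2)
  expect_equal(disp_norm <- sqrt((gt$row - ctr[1])^2 + (gt$col - ctr[2])^2),
               sqrt((40 - ctr[1])^2 + (20 - ctr[2])^2), tolerance = 1e-9)
})
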