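test_that("tolerance gate accepts inclusively and records the sentinel", {
  g0 <- tolerance_gate(c(10, 10), c(10, 10), 20)
  expect_true(g0$accept)
  g_far <- tolerance_gate(c(10, 10), c(35, 10), 20)  # 25 px jump
  expect_false(g_far$accept)
  expect_equal(c(g_far$row, g_far$col), c(0, 0))
  g_eq <- tolerance_gate(c(10, 10), c(10, 15), 5)    # exactly the tolerance
  expect_true(g_eq$accept)
  expect_error(tolerance_gate(c(1, 1), c(1, 1), 0.5),
               class = "echotrack_config_error")
  expect_error(track_config(tolerance = 25), class = "echotrack_config_error")
})

test_that("static sequences track in place; every frame has a record", {
  f <- std_frame(128, seed = 7)
  frames <- list(f, f, f, f)
  k <- std_features(128, seed = 7)
  seeds <- data.frame(point_id = 1:3, row = k$row[1:3], col = k$col[1:3])
  tr <- track_sequence(frames, seeds, track_config())
  expect_equal(nrow(tr), 12)                       # 3 points x 4 frames
  expect_equal(as.vector(table(tr$point_id)), rep(4L, 3))
  td <- tidy(tr)
  for (p in 1:3) {
    d <- td[td$point_id == p & !td$lost, ]
    expect_equal(nrow(d), 4)
    expect_lt(max(sqrt((d$row - seeds$row[p])^2 + (d$col - seeds$col[p])^2)),
              0.5)
  }
  g <- glance(tr)
  expect_equal(g$full_trajectories, 3)
  expect_equal(g$lost_records, 0)
})

test_that("gate soundness holds in the emitted table", {
  sq <- make_sequence(std_spec(128, seed = 7),
                      motion_model("translation", shift = c(1, 0)), 6)
  k <- std_features(128, seed = 7)
  ki <- k[k$row > 25 & k$row < 95 & k$col > 25 & k$col < 103, ]
  seeds <- data.frame(point_id = seq_len(min(4, nrow(ki))),
                      row = ki$row[seq_len(min(4, nrow(ki)))],
                      col = ki$col[seq_len(min(4, nrow(ki)))])
  tr <- track_sequence(sq$frames, seeds, track_config(tolerance = 5))
  td <- tidy(tr)
  for (p in unique(td$point_id)) {
    d <- td[td$point_id == p, ][order(td$frame[td$point_id == p]), ]
    ok <- !d$lost[-1] & !d$lost[-nrow(d)]
    steps <- sqrt(diff(d$row)^2 + diff(d$col)^2)[ok]
    expect_true(all(steps <= 5 + 1e-9))
  }
})

test_that("jumps beyond the tolerance yield lost sentinels; smaller ones pass", {
  f <- std_frame(96, seed = 9)
  jump7 <- shift_int(f, 7, 0)
  k <- detect_keypoints(f)
  ki <- k[k$row > 25 & k$row < 70 & k$col > 25 & k$col < 70, ]
  seeds <- data.frame(point_id = 1:2, row = ki$row[1:2], col = ki$col[1:2])
  frames <- list(f, f, jump7, jump7)
  tr5 <- track_sequence(frames, seeds, track_config(tolerance = 5))
  tr10 <- track_sequence(frames, seeds, track_config(tolerance = 10))
  td5 <- tidy(tr5); td10 <- tidy(tr10)
  # the 7 px jump exceeds tolerance 5 (lost, sentinel) but not tolerance 10
  expect_true(all(td5$lost[td5$frame == 3]))
  expect_true(all(td5$row[td5$frame == 3] == 0 & td5$col[td5$frame == 3] == 0))
  expect_false(any(td10$lost[td10$frame == 3]))
  # raising the tolerance never increases the number of lost records
  expect_lte(sum(td10$lost), sum(td5$lost))
})

test_that("a featureless frame loses all points but tracking continues", {
  f <- std_frame(96, seed = 9)
  blank <- matrix(0, 96, 96)
  k <- detect_keypoints(f)
  ki <- k[k$row > 30 & k$row < 66 & k$col > 30 & k$col < 66, ]
  seeds <- data.frame(point_id = 1:2, row = ki$row[1:2], col = ki$col[1:2])
  tr <- suppressWarnings(
    track_sequence(list(f, blank, f, f), seeds,
                   track_config(reacquire = TRUE, refine_with_lk = FALSE))
  )
  td <- tidy(tr)
  expect_true(all(td$lost[td$frame == 2]))   # nothing to match into
  expect_true(all(td$lost[td$frame == 3]))   # nothing to match from
  expect_false(any(td$lost[td$frame == 4]))  # re-acquired near the anchor
})

test_that("trajectories round-trip through the Table-1-style CSV", {
  f <- std_frame(96, seed = 9)
  jump <- shift_int(f, 30, 0)
  k <- detect_keypoints(f)
  ki <- k[k$row > 30 & k$row < 60 & k$col > 30 & k$col < 66, ]
  seeds <- data.frame(point_id = 1L, row = ki$row[1], col = ki$col[1])
  tr <- track_sequence(list(f, f, jump), seeds, track_config(tolerance = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  export_trajectories(tr, path)
  raw <- utils::read.csv(path)
  expect_named(raw, c("point_id", "frame", "abscissa", "ordinate", "lost"))
  expect_equal(nrow(raw), 3)
  lost_row <- raw[raw$lost, ]
  expect_equal(nrow(lost_row), 1)
  expect_equal(c(lost_row$abscissa, lost_row$ordinate), c(0, 0))
  back <- import_trajectories(path)
  expect_equal(back$row, tr$row)
  expect_equal(back$col, tr$col)
  expect_equal(back$lost, tr$lost)
  expect_error(export_trajectories(tr[0, ], path), class = "echotrack_error")
})

test_that("contraction curve is flat when static and dips at half period", {
  # static trajectories: constant 1
  td <- tibble::tibble(point_id = rep(1:3, each = 4),
                       frame = rep(1:4, 3),
                       row = rep(c(10, 20, 30), each = 4),
                       col = rep(c(10, 25, 15), each = 4),
                       lost = FALSE)
  cc <- contraction_curve(td)
  expect_equal(cc$value, rep(1, 4), tolerance = 1e-12)
  # ground-truth trajectories of a contracting motion dip at frame 11
  m <- motion_model("periodic_radial", amplitude = 3, period = 20)
  pts <- expand.grid(row = c(20, 40, 60), col = c(20, 40, 60))
  gt <- dplyr::bind_rows(lapply(0:20, function(t) {
    p <- motion_apply(m, t, pts, 80, 80)
    tibble::tibble(point_id = seq_len(nrow(pts)), frame = t + 1L,
                   row = p$row, col = p$col, lost = FALSE)
  }))
  cc2 <- contraction_curve(gt)
  expect_equal(cc2$frame[which.min(cc2$value)], 11, tolerance = 1)
  expect_equal(cc2$value[1], 1)
  expect_equal(cc2$value[21], 1, tolerance = 1e-9)
  # a single trajectory equals its own distance series
  one <- gt[gt$point_id == 1, ]
  cc3 <- contraction_curve(one, reference = c(40.5, 40.5))
  d1 <- sqrt((one$row - 40.5)^2 + (one$col - 40.5)^2)
  expect_equal(cc3$value, d1 / d1[1], tolerance = 1e-12)
})
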