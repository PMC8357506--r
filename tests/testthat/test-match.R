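test_that("euclidean distance and ratio test follow their definitions", {
  expect_equal(euclidean_distance(c(0, 3, 4), c(0, 0, 0)), 5)
  expect_equal(euclidean_distance(1:4, 1:4), 0)
  set.seed(2)
  a <- rnorm(128); b <- rnorm(128)
  expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
  expect_error(euclidean_distance(1:3, 1:4), class = "echotrack_error")
  expect_true(ratio_test(2, 10, 0.44)$success)     # r = 0.2
  expect_false(ratio_test(4.5, 10, 0.44)$success)  # r = 0.45 >= eta
  expect_equal(ratio_test(4.5, 10)$r, 0.45)
  expect_true(ratio_test(0, 10)$success)           # exact duplicate
  expect_warning(amb <- ratio_test(0, 0), "ambiguous")
  expect_false(amb$success)
})

test_that("identical descriptor sets match themselves perfectly", {
  set.seed(8)
  d <- matrix(abs(rnorm(10 * 128)), 10, 128)
  d <- d / sqrt(rowSums(d^2))
  m <- match_images(d, d)
  expect_equal(nrow(m), 10)
  expect_equal(m$index_a, m$index_b)
  expect_equal(m$d_min, rep(0, 10))
  expect_true(all(m$r < 0.44))
})

test_that("only the uncorrupted descriptor survives heavy noise", {
  set.seed(9)
  a <- matrix(abs(rnorm(8 * 128)), 8, 128); a <- a / sqrt(rowSums(a^2))
  b <- matrix(abs(rnorm(8 * 128)), 8, 128); b <- b / sqrt(rowSums(b^2))
  b[1, ] <- a[1, ]   # one exact correspondence among decoys
  m <- match_images(a, b)
  expect_equal(nrow(m), 1)
  expect_equal(m$index_a, 1)
  expect_equal(m$index_b, 1)
})

test_that("tightening the ratio threshold never adds matches", {
  fa <- std_features(128, seed = 7)
  sq <- make_sequence(std_spec(128, seed = 7),
                      motion_model("translation", shift = c(1, -1)), 2)
  fb <- cached("feats_128_7_shift11", sift_features(sq$frames[[2]]))
  n_prev <- Inf
  for (eta in c(0.44, 0.3, 0.2)) {
    n <- nrow(match_images(fa, fb, match_config(ratio_threshold = eta)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  # every accepted pair satisfies r < eta and d_min <= d_min2
  m <- match_images(fa, fb)
  expect_true(all(m$r < 0.44))
  expect_true(all(m$d_min <= m$d_min2))
})

test_that("many-to-one collisions resolve to the smallest distance", {
  set.seed(10)
  base <- matrix(abs(rnorm(6 * 128)), 6, 128)
  base <- base / sqrt(rowSums(base^2))
  a <- rbind(base[1, ], base[1, ] + 0.001, base[2:4, ])
  a <- a / sqrt(rowSums(a^2))
  m_on <- match_images(a, base, match_config(mutual = TRUE))
  m_off <- match_images(a, base, match_config(mutual = FALSE))
  expect_gte(nrow(m_off), nrow(m_on))
  expect_false(any(duplicated(m_on$index_b)))
})

test_that("kd-tree structure is balanced and degenerate cases handled", {
  set.seed(11)
  for (n in c(17, 64, 200)) {
    d <- matrix(rnorm(n * 16), n, 16)
    tree <- build_kdtree(d, leaf_size = 1L)
    expect_lte(echotrack:::kdtree_depth(tree$root), ceiling(log2(n)) + 1)
  }
  single <- build_kdtree(matrix(runif(128), 1, 128))
  r <- bbf_nearest2(single, runif(128))
  expect_equal(r$id_min, 1)
  expect_equal(r$d_min2, Inf)
  same <- build_kdtree(matrix(1, 5, 8))
  rs <- bbf_nearest2(same, rep(1, 8))
  expect_equal(rs$d_min, 0)
  expect_error(build_kdtree(matrix(numeric(0), 0, 8)),
               class = "echotrack_error")
})

test_that("exhaustive BBF reproduces brute force exactly", {
  set.seed(12)
  d <- matrix(abs(rnorm(60 * 32)), 60, 32)
  tree <- build_kdtree(d)
  for (i in 1:25) {
    q <- abs(rnorm(32))
    dd <- sqrt(colSums((t(d) - q)^2))
    o <- order(dd)
    ex <- bbf_nearest2(tree, q, max_checks = Inf)
    expect_equal(ex$id_min, o[1])
    expect_equal(ex$d_min, dd[o[1]], tolerance = 1e-12)
    expect_equal(ex$d_min2, dd[o[2]], tolerance = 1e-12)
  }
  # a stored point queries back to itself at distance zero
  self <- bbf_nearest2(tree, d[7, ], max_checks = 5)
  expect_equal(self$d_min, 0)
  expect_equal(self$id_min, 7)
})

test_that("kdtree_bbf search mode agrees with brute force matching", {
  fa <- std_features(128, seed = 7)
  sq <- make_sequence(std_spec(128, seed = 7),
                      motion_model("translation", shift = c(1, -1)), 2)
  fb <- cached("feats_128_7_shift11", sift_features(sq$frames[[2]]))
  m_bf <- match_images(fa, fb, match_config(search = "brute_force"))
  m_kd <- match_images(fa, fb, match_config(search = "kdtree_bbf",
                                            bbf_max_checks = 10000L))
  expect_equal(m_kd$index_a, m_bf$index_a)
  expect_equal(m_kd$index_b, m_bf$index_b)
  expect_equal(m_kd$d_min, m_bf$d_min, tolerance = 1e-9)
})

test_that("reverse matching mirrors forward matching on identical sets", {
  set.seed(13)
  d <- matrix(abs(rnorm(12 * 128)), 12, 128); d <- d / sqrt(rowSums(d^2))
  rc <- reverse_match_check(d, d)
  expect_equal(rc$forward, rc$reverse)
  expect_equal(rc$forward, 12)
  # disjoint random clouds barely match
  a <- matrix(abs(rnorm(30 * 128)), 30, 128); a <- a / sqrt(rowSums(a^2))
  b <- matrix(abs(rnorm(30 * 128)), 30, 128); b <- b / sqrt(rowSums(b^2))
  rc2 <- reverse_match_check(a, b)
  expect_lte(rc2$forward, 3)
  expect_lte(rc2$reverse, 3)
})
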