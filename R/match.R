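# Descriptor matching: Euclidean nearest neighbors, the ratio test
# r = d_min / d_min2 < eta (eta = 0.44 by default), via brute force or
# K-D tree + BBF search.

#' Configure feature matching
#'
#' @param ratio_threshold Ratio-test threshold `eta` in (0, 1); a candidate
#'   is accepted when its nearest/second-nearest distance ratio is strictly
#'   below it. Default 0.44.
#' @param search `"brute_force"` (exact) or `"kdtree_bbf"` (approximate).
#' @param bbf_max_checks Leaf-point budget for BBF search.
#' @param mutual If `TRUE` (default), resolve many-to-one collisions: when
#'   several source keypoints accept the same target, only the pair with the
#'   smallest `d_min` is kept. `FALSE` reproduces the literal one-directional
#'   flow.
#' @return An object of class `match_config`.
#' @export
match_config <- function(ratio_threshold = 0.44,
                         search = c("brute_force", "kdtree_bbf"),
                         bbf_max_checks = 200L, mutual = TRUE) {
  if (ratio_threshold <= 0 || ratio_threshold >= 1) {
    abort("`ratio_threshold` must lie strictly in (0, 1)",
          class = "echotrack_config_error")
  }
  bbf_max_checks <- as.integer(min(bbf_max_checks, .Machine$integer.max))
  if (is.na(bbf_max_checks) || bbf_max_checks < 1) {
    abort("`bbf_max_checks` must be >= 1", class = "echotrack_config_error")
  }
  structure(list(ratio_threshold = ratio_threshold,
                 search = match.arg(search),
                 bbf_max_checks = bbf_max_checks, mutual = mutual),
            class = "match_config")
}

#' Euclidean distance between two descriptor vectors
#'
#' `s(a, b) = sqrt(sum_i (a_i - b_i)^2)`.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    abort("vectors must have equal dimension", class = "echotrack_error")
  }
  sqrt(sum((a - b)^2))
}

#' Nearest/second-nearest ratio test
#'
#' Success iff `d_min / d_min2 < eta`. A duplicate pair with both distances
#' zero is ambiguous (the ratio is undefined) and reported as failure.
#'
#' @param d_min,d_min2 Nearest and second-nearest distances
#'   (`d_min <= d_min2`).
#' @param eta Threshold in (0, 1).
#' @return List with `success` (logical) and `r` (the ratio; `NaN` in the
#'   ambiguous 0/0 case).
#' @export
ratio_test <- function(d_min, d_min2, eta = 0.44) {
  if (d_min2 == 0) {
    if (d_min == 0) {
      warn("ambiguous duplicate: d_min = d_min2 = 0; reported as failure")
      return(list(success = FALSE, r = NaN))
    }
    abort("`d_min2` must be >= `d_min`", class = "echotrack_error")
  }
  r <- d_min / d_min2
  list(success = is.finite(r) && r < eta, r = r)
}

# Extract the descriptor matrix (and ids) from a sift_features() tibble or a
# bare matrix.
as_descriptor_set <- function(x) {
  if (is.matrix(x)) {
    list(desc = x, id = seq_len(nrow(x)),
          row = rep(NA_real_, nrow(x)), col = rep(NA_real_, nrow(x)))
  } else if (is.data.frame(x) && !is.null(x$desc)) {
    list(desc = x$desc, id = if (!is.null(x$id)) x$id else seq_len(nrow(x)),
         row = if (!is.null(x$row)) x$row else rep(NA_real_, nrow(x)),
         col = if (!is.null(x$col)) x$col else rep(NA_real_, nrow(x)))
  } else {
    abort("descriptor set must be a matrix or a tibble with a `desc` column",
          class = "echotrack_error")
  }
}

empty_matches <- function() {
  tibble(index_a = integer(), index_b = integer(), d_min = numeric(),
         d_min2 = numeric(), r = numeric(),
         row_a = numeric(), col_a = numeric(),
         row_b = numeric(), col_b = numeric())
}

#' Match two descriptor sets
#'
#' For every descriptor in `a`, finds its two nearest neighbors in `b`
#' (exactly, or approximately with BBF) and accepts the pair when the ratio
#' test passes. With `cfg$mutual`, many-to-one collisions on the same target
#' keypoint keep only the pair with the smallest distance.
#'
#' @param a,b Descriptor sets: [sift_features()] tibbles (with `desc`) or
#'   bare descriptor matrices.
#' @param cfg A [match_config()].
#' @return A tibble of accepted pairs: `index_a`, `index_b` (keypoint ids),
#'   `d_min`, `d_min2`, `r`, and the keypoint coordinates `row_a`, `col_a`,
#'   `row_b`, `col_b` when available.
#' @export
match_images <- function(a, b, cfg = match_config()) {
  stopifnot(inherits(cfg, "match_config"))
  sa <- as_descriptor_set(a); sb <- as_descriptor_set(b)
  na <- nrow(sa$desc); nb <- nrow(sb$desc)
  if (na == 0) return(empty_matches())
  if (nb < 2) {
    warn("fewer than 2 descriptors in the target set: no ratio test possible")
    return(empty_matches())
  }
  if (cfg$search == "brute_force") {
    # exact per-row distances (the |a|^2 + |b|^2 - 2ab identity loses
    # precision catastrophically for near-duplicate descriptors)
    tb <- t(sb$desc)
    d1 <- d2 <- numeric(na); i1 <- i2 <- integer(na)
    for (i in seq_len(na)) {
      dd <- sqrt(colSums((tb - sa$desc[i, ])^2))
      j1 <- which.min(dd)
      i1[i] <- j1; d1[i] <- dd[j1]
      dd[j1] <- Inf
      j2 <- which.min(dd)
      i2[i] <- j2; d2[i] <- dd[j2]
    }
  } else {
    tree <- build_kdtree(sb$desc)
    res <- lapply(seq_len(na), function(i) {
      bbf_nearest2(tree, sa$desc[i, ], cfg$bbf_max_checks)
    })
    d1 <- vapply(res, `[[`, numeric(1), "d_min")
    d2 <- vapply(res, `[[`, numeric(1), "d_min2")
    i1 <- vapply(res, `[[`, numeric(1), "id_min")
    i2 <- vapply(res, `[[`, numeric(1), "id_min2")
  }
  r <- ifelse(d2 > 0, d1 / d2, ifelse(d1 == 0, NaN, Inf))
  ok <- is.finite(r) & r < cfg$ratio_threshold & !is.na(i1)
  m <- tibble(index_a = sa$id[seq_len(na)][ok],
              index_b = sb$id[i1[ok]],
              d_min = d1[ok], d_min2 = d2[ok], r = r[ok],
              row_a = sa$row[seq_len(na)][ok], col_a = sa$col[seq_len(na)][ok],
              row_b = sb$row[i1[ok]], col_b = sb$col[i1[ok]])
  if (cfg$mutual && nrow(m) > 1) {
    m <- dplyr::arrange(m, .data$d_min, .data$index_a)
    m <- m[!duplicated(m$index_b), , drop = FALSE]
    m <- dplyr::arrange(m, .data$index_a)
  }
  m
}

#' Forward and reverse match counts
#'
#' Runs [match_images()] in both directions (A as source against B, then B
#' against A). Near-equal counts indicate that the two frames can serve as
#' templates for each other — an internal-consistency audit of the matcher.
#'
#' @param a,b Descriptor sets (see [match_images()]).
#' @param cfg A [match_config()].
#' @return List with `forward` and `reverse` counts and the two match
#'   tibbles (`matches_forward`, `matches_reverse`).
#' @export
reverse_match_check <- function(a, b, cfg = match_config()) {
  mf <- match_images(a, b, cfg)
  mr <- match_images(b, a, cfg)
  list(forward = nrow(mf), reverse = nrow(mr),
       matches_forward = mf, matches_reverse = mr)
}
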