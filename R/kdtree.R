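# K-D tree with Best-Bin-First (BBF) approximate nearest-neighbor search.
#
# High-dimensional descriptor matching is dominated by backtracking in exact
# K-D tree search; BBF instead visits leaves in order of the distance from
# the query to each bin's boundary and stops after a fixed number of leaf
# examinations, which finds the true nearest neighbor with high probability
# at a fraction of the cost.

#' Build a K-D tree over descriptor vectors
#'
#' Splits recursively on the dimension of highest variance at its median;
#' points equal to the median go right, which balances the tree so its depth
#' is at most about `log2(n) + 1`.
#'
#' @param descriptors Numeric matrix, one descriptor per row.
#' @param leaf_size Maximum points held in a leaf.
#' @return An object of class `kdtree`.
#' @export
build_kdtree <- function(descriptors, leaf_size = 4L) {
  if (!is.matrix(descriptors) || nrow(descriptors) == 0) {
    abort("`descriptors` must be a non-empty numeric matrix",
          class = "echotrack_error")
  }
  build <- function(idx) {
    if (length(idx) <= leaf_size) {
      return(list(leaf = TRUE, idx = idx))
    }
    vars <- apply(descriptors[idx, , drop = FALSE], 2, stats::var)
    dim_ <- which.max(vars)
    vals <- descriptors[idx, dim_]
    if (max(vals) == min(vals)) {          # all points identical on every
      return(list(leaf = TRUE, idx = idx)) # high-variance axis: stop
    }
    split <- stats::median(vals)
    left <- idx[vals < split]
    right <- idx[vals >= split]
    if (length(left) == 0 || length(right) == 0) {
      # median equal to min: split strictly below/at-or-above the midpoint
      split <- (max(vals) + min(vals)) / 2
      left <- idx[vals < split]
      right <- idx[vals >= split]
    }
    list(leaf = FALSE, dim = dim_, split = split,
         left = build(left), right = build(right))
  }
  structure(list(root = build(seq_len(nrow(descriptors))),
                 data = descriptors),
            class = "kdtree")
}

kdtree_depth <- function(node) {
  if (isTRUE(node$leaf)) return(1L)
  1L + max(kdtree_depth(node$left), kdtree_depth(node$right))
}

#' Two nearest neighbors by Best-Bin-First search
#'
#' Descends to the query's own bin first, queuing the sibling branch of every
#' split with priority equal to the accumulated distance from the query to
#' the branch's bounding box, then repeatedly pops the closest unexplored
#' bin. Search stops after `max_checks` leaf bins have been examined (or the
#' queue empties, which makes the result exact — so any `max_checks >= n`
#' reproduces brute force). Returns the best two distinct stored points.
#'
#' @param tree A [build_kdtree()] result.
#' @param query Numeric vector of the tree's dimension.
#' @param max_checks Leaf-bin examination budget (`Inf` for exact search).
#' @return List with `d_min`, `d_min2` (Euclidean; `Inf` when fewer than two
#'   points exist or were reached), `id_min`, `id_min2` (row indices).
#' @export
bbf_nearest2 <- function(tree, query, max_checks = 200L) {
  stopifnot(inherits(tree, "kdtree"))
  data <- tree$data
  if (length(query) != ncol(data)) {
    abort("query dimension does not match the tree",
          class = "echotrack_error")
  }
  best <- list(d1 = Inf, i1 = NA_integer_, d2 = Inf, i2 = NA_integer_)
  ndim <- ncol(data)
  # priority queue as parallel lists (small n: linear ops are fine); each
  # entry carries the accumulated squared distance from the query to the
  # bin's bounding hyperrectangle plus the per-dimension offsets behind it
  q_node <- list(tree$root); q_pri <- 0
  q_off <- list(numeric(ndim))
  checks <- 0L
  while (length(q_node) > 0 && checks < max_checks) {
    j <- which.min(q_pri)
    node <- q_node[[j]]
    bound <- q_pri[j]; off <- q_off[[j]]
    q_node[[j]] <- NULL; q_pri <- q_pri[-j]; q_off[[j]] <- NULL
    if (bound >= best$d2^2) next   # bin cannot improve the two best
    # descend to this subtree's leaf, queueing far branches
    while (!isTRUE(node$leaf)) {
      split_dim <- node$dim
      diff <- query[split_dim] - node$split
      if (diff < 0) {
        far <- node$right; node <- node$left
      } else {
        far <- node$left; node <- node$right
      }
      far_off <- off
      far_off[split_dim] <- diff
      q_node[[length(q_node) + 1]] <- far
      q_pri <- c(q_pri, bound - off[split_dim]^2 + diff^2)
      q_off[[length(q_off) + 1]] <- far_off
    }
    pts <- data[node$idx, , drop = FALSE]
    d <- sqrt(rowSums(sweep(pts, 2, query)^2))
    checks <- checks + 1L
    for (kk in order(d)[seq_len(min(2, length(d)))]) {
      di <- d[kk]; ii <- node$idx[kk]
      if (di < best$d1) {
        best$d2 <- best$d1; best$i2 <- best$i1
        best$d1 <- di; best$i1 <- ii
      } else if (di < best$d2 && ii != best$i1) {
        best$d2 <- di; best$i2 <- ii
      }
    }
  }
  list(d_min = best$d1, d_min2 = best$d2,
       id_min = best$i1, id_min2 = best$i2)
}
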