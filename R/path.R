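#' Weight of a directed edge between two retained cells
#'
#' The graph over retained cells connects every componentwise non-decreasing
#' (and non-identical) pair of cells. The edge weight is the product of the two
#' node frequencies divided by the edge length, where length is the Euclidean
#' distance in grid-index space — so weights do not depend on the RT units of
#' either axis.
#'
#' @param u,v Single-row data frames (or lists) with `ix`, `iy`, `freq`.
#'
#' @return Positive edge weight.
#' @export
edge_weight <- function(u, v) {
  if (v$ix < u$ix || v$iy < u$iy) {
    stop("edge must be ascending: v >= u in both indices", call. = FALSE)
  }
  d <- sqrt((v$ix - u$ix)^2 + (v$iy - u$iy)^2)
  if (d == 0) stop("invalid edge: zero length (u == v)", call. = FALSE)
  (u$freq * v$freq) / d
}

# relative tolerance for "equal weight" ties in the path search
.path_eps <- function(w) 1e-9 * max(1, abs(w))

# lexicographic comparison of two (ix, iy) node-index sequences; returns
# -1 if a < b, 0 if equal, 1 if a > b
compare_node_seq <- function(a_ix, a_iy, b_ix, b_iy) {
  na <- length(a_ix); nb <- length(b_ix)
  for (k in seq_len(min(na, nb))) {
    if (a_ix[k] != b_ix[k]) return(sign(a_ix[k] - b_ix[k]))
    if (a_iy[k] != b_iy[k]) return(sign(a_iy[k] - b_iy[k]))
  }
  sign(na - nb)
}

#' Maximum-weight ascending path through retained cells
#'
#' Builds the weighted DAG whose nodes are the retained grid cells and whose
#' edges connect every comparable pair (terminal cell not smaller than the
#' start cell in both grid dimensions), and returns the path maximizing the
#' sum of edge weights, by dynamic programming in topological `(ix, iy)` order.
#' This is the noise-rejection core: dense, monotonically arranged signal cells
#' chain into short high-frequency hops while scattered noise cells contribute
#' little weight.
#'
#' A single node is a valid path of weight 0. Ties between equal-weight optima
#' prefer the path with more nodes, then the lexicographically smallest
#' `(ix, iy)` node sequence, so the result is deterministic.
#'
#' @param nodes Data frame with columns `ix`, `iy`, `freq` (and optionally
#'   `x`, `y` carried through), one row per retained cell.
#'
#' @return A list of class `ascending_path`: `nodes` (rows of `nodes` along
#'   the path, in path order) and `total_weight`.
#' @export
max_weight_path <- function(nodes) {
  n <- nrow(nodes)
  if (is.null(n) || n < 1L) stop("empty node set", call. = FALSE)
  ord <- order(nodes$ix, nodes$iy)
  nodes <- nodes[ord, , drop = FALSE]
  ix <- nodes$ix; iy <- nodes$iy; freq <- as.numeric(nodes$freq)

  best_w <- numeric(n)      # best path weight ending at node j
  best_len <- rep(1L, n)    # number of nodes on that path
  pred <- rep(NA_integer_, n)

  path_to <- function(j) {  # indices along the best path ending at j
    out <- integer(0)
    while (!is.na(j)) { out <- c(j, out); j <- pred[j] }
    out
  }

  for (j in seq_len(n)) {
    if (j == 1L) next
    js <- seq_len(j - 1L)
    ok <- ix[js] <= ix[j] & iy[js] <= iy[j] &
      !(ix[js] == ix[j] & iy[js] == iy[j])
    if (!any(ok)) next
    js <- js[ok]
    d <- sqrt((ix[j] - ix[js])^2 + (iy[j] - iy[js])^2)
    cand <- best_w[js] + freq[js] * freq[j] / d
    m <- max(cand)
    tied <- js[cand >= m - .path_eps(m)]
    if (length(tied) > 1L) {
      # prefer longer path, then lexicographically smallest node sequence
      lens <- best_len[tied]
      tied <- tied[lens == max(lens)]
      if (length(tied) > 1L) {
        best_i <- tied[1]
        bp <- path_to(best_i)
        for (i in tied[-1]) {
          p <- path_to(i)
          if (compare_node_seq(ix[p], iy[p], ix[bp], iy[bp]) < 0) {
            best_i <- i; bp <- p
          }
        }
        tied <- best_i
      }
    }
    i <- tied[1]
    best_w[j] <- best_w[i] + freq[i] * freq[j] / sqrt((ix[j] - ix[i])^2 +
                                                        (iy[j] - iy[i])^2)
    best_len[j] <- best_len[i] + 1L
    pred[j] <- i
  }

  gm <- max(best_w)
  ends <- which(best_w >= gm - .path_eps(gm))
  if (length(ends) > 1L) {
    lens <- best_len[ends]
    ends <- ends[lens == max(lens)]
    if (length(ends) > 1L) {
      best_e <- ends[1]; bp <- path_to(best_e)
      for (e in ends[-1]) {
        p <- path_to(e)
        if (compare_node_seq(ix[p], iy[p], ix[bp], iy[bp]) < 0) {
          best_e <- e; bp <- p
        }
      }
      ends <- best_e
    }
  }
  e <- ends[1]
  idx <- path_to(e)
  structure(list(nodes = nodes[idx, , drop = FALSE],
                 total_weight = best_w[e]),
            class = "ascending_path")
}

#' @export
print.ascending_path <- function(x, ...) {
  cat(sprintf("<ascending_path> %d node(s), total weight %.6g\n",
              nrow(x$nodes), x$total_weight))
  invisible(x)
}
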