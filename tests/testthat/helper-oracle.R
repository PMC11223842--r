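# Independent brute-force oracle for the maximum-weight ascending path:
# enumerates every monotone path (chain) over the node set explicitly and
# applies the same tie rule as the package contract (max weight, then more
# nodes, then lexicographically smallest (ix, iy) sequence).

oracle_seq_less <- function(a_ix, a_iy, b_ix, b_iy) {
  for (k in seq_len(min(length(a_ix), length(b_ix)))) {
    if (a_ix[k] != b_ix[k]) return(a_ix[k] < b_ix[k])
    if (a_iy[k] != b_iy[k]) return(a_iy[k] < b_iy[k])
  }
  length(a_ix) < length(b_ix)
}

oracle_max_weight_path <- function(nodes) {
  ix <- nodes$ix; iy <- nodes$iy; f <- as.numeric(nodes$freq)
  n <- length(ix)
  best <- NULL

  consider <- function(idx, w) {
    if (is.null(best)) { best <<- list(idx = idx, w = w); return() }
    eps <- 1e-9 * max(1, abs(w), abs(best$w))
    if (w > best$w + eps) { best <<- list(idx = idx, w = w); return() }
    if (w >= best$w - eps) {
      if (length(idx) > length(best$idx)) {
        best <<- list(idx = idx, w = w)
      } else if (length(idx) == length(best$idx) &&
                 oracle_seq_less(ix[idx], iy[idx],
                                 ix[best$idx], iy[best$idx])) {
        best <<- list(idx = idx, w = w)
      }
    }
  }

  extend <- function(idx, w) {
    consider(idx, w)
    last <- idx[length(idx)]
    succ <- which(ix >= ix[last] & iy >= iy[last] &
                    !(ix == ix[last] & iy == iy[last]))
    for (s in succ) {
      d <- sqrt((ix[s] - ix[last])^2 + (iy[s] - iy[last])^2)
      extend(c(idx, s), w + f[last] * f[s] / d)
    }
  }

  for (i in seq_len(n)) extend(i, 0)
  list(nodes = nodes[best$idx, , drop = FALSE], total_weight = best$w)
}

# random set of distinct grid cells for oracle comparisons
random_node_set <- function(max_nodes = 10L, coord_max = 7L) {
  k <- sample.int(max_nodes, 1L)
  cells <- expand.grid(ix = 0:coord_max, iy = 0:coord_max)
  pick <- cells[sample.int(nrow(cells), k), ]
  data.frame(ix = pick$ix, iy = pick$iy,
             x = as.numeric(pick$ix), y = as.numeric(pick$iy),
             freq = sample(1:5, k, replace = TRUE))
}
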