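#' Grid specification for the calibration plane
#'
#' Equal-width bin edges over the observed range of each dimension. Bins are
#' half-open `[edge_i, edge_{i+1})` except the last, which is closed so the
#' maximum falls in the top bin (the usual histogram convention).
#'
#' @param points A [calibration_points] object (or data frame with
#'   `library_rt`, `measured_rt`).
#' @param size_x,size_y Number of cells per axis (default 100, as used for the
#'   calibration grid).
#'
#' @return A list of class `grid_spec` with `size_x`, `size_y`, `x_edges`,
#'   `y_edges`.
#' @export
grid_spec <- function(points, size_x = 100L, size_y = size_x) {
  size_x <- as.integer(size_x); size_y <- as.integer(size_y)
  if (size_x < 2L || size_y < 2L) stop("grid size must be >= 2", call. = FALSE)
  xr <- range(points$library_rt)
  yr <- range(points$measured_rt)
  if (diff(xr) <= 0) {
    stop("degenerate range: all library_rt values identical", call. = FALSE)
  }
  if (diff(yr) <= 0) {
    stop("degenerate range: all measured_rt values identical", call. = FALSE)
  }
  structure(
    list(size_x = size_x, size_y = size_y,
         x_edges = seq(xr[1], xr[2], length.out = size_x + 1L),
         y_edges = seq(yr[1], yr[2], length.out = size_y + 1L)),
    class = "grid_spec"
  )
}

bin_index <- function(v, edges) {
  # [e_i, e_{i+1}) with the last bin closed on the right
  i <- findInterval(v, edges, rightmost.closed = TRUE)
  pmin.int(pmax.int(i, 1L), length(edges) - 1L)
}

#' Count calibration points per grid cell
#'
#' Step 1 of the calibration workflow: assign every point to exactly one cell
#' and count per-cell frequencies. The total count is conserved.
#'
#' @param points A [calibration_points] object.
#' @param spec A [grid_spec]; defaults to a 100x100 grid over the data range.
#'
#' @return A list of class `grid_summary`: `counts` (size_y x size_x integer
#'   matrix, rows indexed by the measured-RT axis), `spec`, and `retained`
#'   (`NULL` until [nonmax_suppress()] fills it).
#' @export
grid_count <- function(points, spec = grid_spec(points)) {
  ix <- bin_index(points$library_rt, spec$x_edges)
  iy <- bin_index(points$measured_rt, spec$y_edges)
  counts <- matrix(0L, nrow = spec$size_y, ncol = spec$size_x)
  cell <- (ix - 1L) * spec$size_y + iy
  nbins <- spec$size_x * spec$size_y
  counts[] <- tabulate(cell, nbins = nbins)
  # per-cell coordinate sums, for member-mean node coordinates
  sum_x <- matrix(0, nrow = spec$size_y, ncol = spec$size_x)
  sum_y <- matrix(0, nrow = spec$size_y, ncol = spec$size_x)
  occ <- sort(unique(cell))
  sum_x[occ] <- vapply(split(points$library_rt, cell), sum, 0)
  sum_y[occ] <- vapply(split(points$measured_rt, cell), sum, 0)
  structure(list(counts = counts, sum_x = sum_x, sum_y = sum_y,
                 spec = spec, retained = NULL),
            class = "grid_summary")
}

#' Row/column non-maximal suppression of grid cells
#'
#' Retains, for every occupied grid row and every occupied grid column, the
#' cell with the maximum count (the union of row maxima and column maxima).
#' Ties keep the first (lowest-index) maximal cell. The retained set has at
#' most `size_x + size_y` cells regardless of the number of raw points, which
#' is what makes the downstream path search independent of data size.
#'
#' @param summary A `grid_summary` from [grid_count()].
#'
#' @return The `grid_summary` with `retained` filled: a data frame with cell
#'   indices `ix`, `iy` (1-based), representative coordinates `x`, `y` in RT
#'   units (the mean of the cell's member points), and `freq` (cell count),
#'   sorted by `(ix, iy)`.
#' @export
nonmax_suppress <- function(summary) {
  counts <- summary$counts
  spec <- summary$spec
  keep <- matrix(FALSE, nrow = nrow(counts), ncol = ncol(counts))
  for (iy in seq_len(nrow(counts))) {
    row <- counts[iy, ]
    if (any(row > 0L)) keep[iy, which.max(row)] <- TRUE
  }
  for (ix in seq_len(ncol(counts))) {
    col <- counts[, ix]
    if (any(col > 0L)) keep[which.max(col), ix] <- TRUE
  }
  idx <- which(keep, arr.ind = TRUE)
  # node coordinate: mean of the cell's member points (no half-cell
  # quantization, unlike the cell center)
  retained <- data.frame(
    ix = as.integer(idx[, "col"]),
    iy = as.integer(idx[, "row"]),
    x = summary$sum_x[idx] / counts[idx],
    y = summary$sum_y[idx] / counts[idx],
    freq = counts[idx]
  )
  retained <- retained[order(retained$ix, retained$iy), , drop = FALSE]
  rownames(retained) <- NULL
  summary$retained <- retained
  summary
}
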