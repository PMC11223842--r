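#' Span filtering of wide-gap path endpoints
#'
#' Because true calibration points are dense mid-gradient and sparse at the
#' extremes, the selected path can end in nodes separated from the rest by a
#' large span; such end nodes are more likely to be noise. When enabled, each
#' end node is dropped if the gap to its inner neighbour exceeds
#' `threshold` times the full data range in either dimension; trimming repeats
#' from the new end until both ends are within the allowable span or only two
#' nodes remain. Interior nodes are never removed, so the output is a
#' contiguous subsequence of the input path. Disabled by default.
#'
#' @param path An `ascending_path` from [max_weight_path()] (or any data frame
#'   of path nodes with `x`, `y` columns in path order).
#' @param x_range,y_range Full range width of the raw data in each dimension.
#' @param enabled Apply the filter? Default `FALSE`.
#' @param threshold Allowable span as a fraction of the full range of both
#'   dimensions; default 0.10.
#'
#' @return An object of the same shape as `path` with end nodes trimmed.
#' @export
filter_span <- function(path, x_range, y_range,
                        enabled = FALSE, threshold = 0.10) {
  if (threshold <= 0 || threshold >= 1) {
    stop("span threshold must be in (0, 1)", call. = FALSE)
  }
  is_path_obj <- inherits(path, "ascending_path")
  nodes <- if (is_path_obj) path$nodes else path
  if (!enabled || nrow(nodes) <= 2L) {
    return(path)
  }
  tx <- threshold * x_range
  ty <- threshold * y_range
  repeat {
    n <- nrow(nodes)
    if (n <= 2L) break
    dropped <- FALSE
    if (abs(nodes$x[2] - nodes$x[1]) > tx ||
        abs(nodes$y[2] - nodes$y[1]) > ty) {
      nodes <- nodes[-1, , drop = FALSE]
      dropped <- TRUE
    }
    n <- nrow(nodes)
    if (n > 2L &&
        (abs(nodes$x[n] - nodes$x[n - 1]) > tx ||
         abs(nodes$y[n] - nodes$y[n - 1]) > ty)) {
      nodes <- nodes[-n, , drop = FALSE]
      dropped <- TRUE
    }
    if (!dropped) break
  }
  rownames(nodes) <- NULL
  if (is_path_obj) {
    path$nodes <- nodes
    path
  } else {
    nodes
  }
}
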