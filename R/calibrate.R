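#' Fit a retention-time calibration curve
#'
#' Runs the full calibration pipeline on paired (library RT/iRT, measured RT)
#' observations: grid the point cloud, keep the row/column maximum cells,
#' extract the maximum-weight ascending path through them, optionally trim
#' wide-span path ends, then fit a frequency-weighted LOESS through the
#' surviving nodes with linear extrapolation beyond both ends. The pipeline is
#' fully deterministic — identical input and configuration give bit-identical
#' models — so it can sit inside an identification loop.
#'
#' Degenerate inputs (fewer than `min_points` pairs, or zero range in either
#' dimension) fall back to an ordinary least-squares line through all points;
#' the returned model is flagged via `model$fallback` and a warning is issued.
#'
#' @param points A [calibration_points] object (or data frame with columns
#'   `library_rt`, `measured_rt`).
#' @param grid_size Cells per axis for the 2-D histogram (default 100).
#' @param span_filter Enable span filtering of wide-gap path ends (default
#'   `FALSE`). Useful when noise can lie outside the true library-RT range.
#' @param span_threshold Allowable end-gap as a fraction of the full range of
#'   both dimensions (default 0.10).
#' @param loess_frac LOESS smoothing fraction (default 0.3).
#' @param min_points Minimum number of pairs for the full pipeline (default 5);
#'   below it the linear fallback is used.
#' @param monotone Apply a cumulative-max projection to the fitted curve
#'   (default `FALSE`; the path constraint already makes the support monotone).
#' @param verbose Log per-stage counts via [message()] (default `FALSE`).
#'
#' @return An `rt_calibration` model. `model$meta` records per-stage counts:
#'   raw points, retained cells, path nodes, post-filter nodes.
#' @export
#'
#' @examples
#' pts <- calibration_points(seq(0, 100, length.out = 500),
#'                           0.5 * seq(0, 100, length.out = 500) + 3)
#' model <- fit_calibration(pts)
#' predict(model, c(10, 50, 90))
fit_calibration <- function(points,
                            grid_size = 100L,
                            span_filter = FALSE,
                            span_threshold = 0.10,
                            loess_frac = 0.3,
                            min_points = 5L,
                            monotone = FALSE,
                            verbose = FALSE) {
  if (grid_size < 2L) stop("grid_size must be >= 2", call. = FALSE)
  if (min_points < 2L) stop("min_points must be >= 2", call. = FALSE)
  x <- points$library_rt
  y <- points$measured_rt
  n <- length(x)
  x_range <- diff(range(x))
  y_range <- diff(range(y))

  if (n < min_points || x_range <= 0 || y_range <= 0) {
    warning("degenerate input (n < min_points or zero range): ",
            "falling back to an ordinary least-squares line", call. = FALSE)
    return(linear_fallback(x, y, loess_frac,
                           meta = list(n_points = n, grid_size = grid_size)))
  }

  spec <- grid_spec(points, size_x = grid_size, size_y = grid_size)
  gs <- nonmax_suppress(grid_count(points, spec))
  path <- max_weight_path(gs$retained)
  filtered <- filter_span(path, x_range = x_range, y_range = y_range,
                          enabled = span_filter, threshold = span_threshold)
  nodes <- filtered$nodes
  if (verbose) {
    message(sprintf(
      "fit_calibration: %d points -> %d retained cells -> %d path nodes -> %d after span filter",
      n, nrow(gs$retained), nrow(path$nodes), nrow(nodes)))
  }
  if (length(unique(nodes$x)) < 2L) {
    warning("path collapsed to a single library-RT position: ",
            "falling back to an ordinary least-squares line", call. = FALSE)
    return(linear_fallback(x, y, loess_frac,
                           meta = list(n_points = n, grid_size = grid_size)))
  }
  model <- fit_loess_curve(nodes$x, nodes$y, w = nodes$freq,
                           frac = loess_frac, monotone = monotone)
  model$meta <- list(
    n_points = n,
    n_retained = nrow(gs$retained),
    n_path = nrow(path$nodes),
    n_filtered = nrow(nodes),
    grid_size = grid_size,
    span_filter = span_filter,
    span_threshold = span_threshold
  )
  model
}

# straight-line model for degenerate inputs; exact on collinear points
linear_fallback <- function(x, y, loess_frac, meta = list()) {
  if (diff(range(x)) <= 0) {
    model <- new_rt_calibration(knots_x = x[1], knots_y = mean(y),
                                loess_frac = loess_frac, fallback = TRUE)
  } else {
    co <- stats::coef(stats::lm(y ~ x))
    kx <- range(x)
    model <- new_rt_calibration(knots_x = kx,
                                knots_y = co[[1]] + co[[2]] * kx,
                                loess_frac = loess_frac, fallback = TRUE)
  }
  model$meta <- c(meta, list(fallback = TRUE))
  model
}

#' Plot a calibration curve over its input points
#'
#' @param x An `rt_calibration` model.
#' @param points Optional [calibration_points] to draw underneath the curve.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rt_calibration <- function(x, points = NULL, ...) {
  if (!is.null(points)) {
    graphics::plot(points$library_rt, points$measured_rt, pch = 16,
                   cex = 0.4, col = "grey60",
                   xlab = "library RT/iRT", ylab = "measured RT (min)", ...)
  } else {
    graphics::plot(x$knots_x, x$knots_y, type = "n",
                   xlab = "library RT/iRT", ylab = "measured RT (min)", ...)
  }
  xs <- seq(min(x$knots_x), max(x$knots_x), length.out = 400)
  graphics::lines(xs, predict(x, xs), col = "firebrick", lwd = 2)
  graphics::points(x$knots_x, x$knots_y, pch = 1, cex = 0.6,
                   col = "firebrick")
  invisible(x)
}

#' Transform library RTs with a fitted calibration model
#'
#' Thin wrapper over [predict.rt_calibration()]; length-preserving.
#'
#' @param model An `rt_calibration` model.
#' @param library_rt Numeric vector of library RT/iRT values.
#' @return Predicted measured RTs.
#' @export
transform_rt <- function(model, library_rt) {
  stopifnot(inherits(model, "rt_calibration"))
  predict(model, library_rt)
}
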