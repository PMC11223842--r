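#' Baseline calibration methods
#'
#' Three generic noise-handling strategies used as comparison points for the
#' grid-and-path calibrator:
#'
#' * `raw_loess` — LOESS straight through all points, no noise removal.
#' * `quantile_loess` — fit a preliminary least-squares line, drop points
#'   whose absolute residual exceeds the `quantile`-th percentile of
#'   residuals (default 95th), then LOESS on the survivors.
#' * `ransac_loess` — random sample consensus with a linear base model
#'   (residual threshold `ransac_threshold` times the y-range, default 5%,
#'   `ransac_iter` candidate draws, seeded so output is deterministic), then
#'   LOESS on the consensus inliers.
#'
#' All three return the same `rt_calibration` model class as
#' [fit_calibration()], so they are interchangeable in the benchmark.
#'
#' @param method One of `"raw_loess"`, `"quantile_loess"`, `"ransac_loess"`.
#' @param points A [calibration_points] object.
#' @param loess_frac LOESS smoothing fraction (default 0.3).
#' @param quantile Residual-quantile cut for `quantile_loess` (default 0.95).
#' @param ransac_threshold Inlier residual threshold as a fraction of the
#'   measured-RT range (default 0.05).
#' @param ransac_iter Number of RANSAC candidate models (default 100).
#' @param seed Seed for the RANSAC draws (default 1).
#'
#' @return An `rt_calibration` model.
#' @export
baseline_fit <- function(method = c("raw_loess", "quantile_loess",
                                    "ransac_loess"),
                         points, loess_frac = 0.3,
                         quantile = 0.95,
                         ransac_threshold = 0.05, ransac_iter = 100L,
                         seed = 1L) {
  method <- match.arg(method)
  x <- points$library_rt
  y <- points$measured_rt
  stopifnot(length(x) >= 2L)
  keep <- switch(
    method,
    raw_loess = rep(TRUE, length(x)),
    quantile_loess = {
      res <- abs(stats::residuals(stats::lm(y ~ x)))
      res <= stats::quantile(res, quantile)
    },
    ransac_loess = ransac_line_inliers(x, y,
                                       threshold = ransac_threshold *
                                         diff(range(y)),
                                       n_iter = ransac_iter, seed = seed)
  )
  model <- fit_loess_curve(x[keep], y[keep], frac = loess_frac)
  model$meta <- list(method = method, n_points = length(x),
                     n_used = sum(keep))
  model
}

# minimal linear RANSAC: repeatedly fit a line through 2 random points, keep
# the candidate with most inliers (|residual| <= threshold), refit by OLS on
# those inliers and return the final inlier mask
ransac_line_inliers <- function(x, y, threshold, n_iter = 100L, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(x)
  best <- NULL
  best_count <- -1L
  for (i in seq_len(n_iter)) {
    ij <- sample.int(n, 2L)
    dx <- x[ij[2]] - x[ij[1]]
    if (dx == 0) next
    slope <- (y[ij[2]] - y[ij[1]]) / dx
    inter <- y[ij[1]] - slope * x[ij[1]]
    inl <- abs(y - (inter + slope * x)) <= threshold
    cnt <- sum(inl)
    if (cnt > best_count) {
      best_count <- cnt
      best <- inl
    }
  }
  if (is.null(best) || best_count < 2L) return(rep(TRUE, n))
  co <- stats::coef(stats::lm(y[best] ~ x[best]))
  final <- abs(y - (co[[1]] + co[[2]] * x)) <= threshold
  if (sum(final) < 2L) best else final
}
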