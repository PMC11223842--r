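#' Generate a ground-truth calibration curve
#'
#' Draws `n` points from one of five monotone non-decreasing curve archetypes
#' observed in real library-vs-measured RT data: linear, distortion at the
#' beginning of elution (slope flattens to zero over the first 15% of the
#' library-RT range), distortion at the end (mirrored), exponential, and
#' S-type (logistic). Library-RT positions are drawn center-dense / end-sparse
#' (truncated normal centered mid-range, sd = range/4), mimicking how peptide
#' identifications cluster mid-gradient, and measured RTs get a small Gaussian
#' jitter (sd = `jitter` times the y-range, default 0.5%).
#'
#' @param curve_type One of `"linear"`, `"distortion_begin"`,
#'   `"distortion_end"`, `"exponential"`, `"s_type"`.
#' @param n Number of points.
#' @param x_range Library-RT range, default `c(0, 100)` (iRT-like units).
#' @param seed Integer seed; fixed seed gives identical output.
#' @param jitter Jitter sd as a fraction of the y-range; set 0 to disable.
#'
#' @return A [calibration_points] object with attribute `is_signal`
#'   (all `TRUE`) and attribute `curve_type`.
#' @export
generate_curve <- function(curve_type = c("linear", "distortion_begin",
                                          "distortion_end", "exponential",
                                          "s_type"),
                           n = 2500L, x_range = c(0, 100), seed = 1L,
                           jitter = 0.005) {
  curve_type <- match.arg(curve_type)
  stopifnot(n >= 1L, diff(x_range) > 0)
  set.seed(as.integer(seed))
  lo <- x_range[1]; hi <- x_range[2]; r <- hi - lo
  # center-dense x: truncated normal by rejection
  x <- numeric(0)
  while (length(x) < n) {
    draw <- stats::rnorm(2L * (n - length(x)), mean = (lo + hi) / 2, sd = r / 4)
    x <- c(x, draw[draw >= lo & draw <= hi])
  }
  x <- x[seq_len(n)]
  y <- true_curve(curve_type, x, lo, hi)
  yr <- diff(range(true_curve(curve_type, c(lo, hi), lo, hi)))
  if (jitter > 0) y <- y + stats::rnorm(n, sd = jitter * yr)
  pts <- calibration_points(x, y)
  attr(pts, "is_signal") <- rep(TRUE, n)
  attr(pts, "curve_type") <- curve_type
  pts
}

# parametric forms: fixed module constants; y in pseudo-minutes
true_curve <- function(curve_type, x, lo, hi) {
  r <- hi - lo
  a <- 1.2; b <- 10  # base gradient: ~10 to ~130 "min" over the x range
  switch(
    curve_type,
    linear = a * x + b,
    distortion_begin = {
      x0 <- lo + 0.15 * r
      y0 <- a * x0 + b
      ifelse(x >= x0, a * x + b,
             y0 - a * (x0 - lo) / 2 + a / (2 * (x0 - lo)) * (x - lo)^2)
    },
    distortion_end = {
      x1 <- hi - 0.15 * r
      y1 <- a * x1 + b
      ifelse(x <= x1, a * x + b,
             y1 + a * (x - x1) - a / (2 * (hi - x1)) * (x - x1)^2)
    },
    exponential = {
      k <- 3 / r
      120 * (exp(k * (x - lo)) - 1) / (exp(3) - 1) + b
    },
    s_type = {
      k <- 10 / r
      120 / (1 + exp(-k * (x - (lo + hi) / 2))) + b
    }
  )
}

#' Subsample signal and inject uniform noise
#'
#' Emulates how calibration input degrades inside an identification engine:
#' only a fraction of the true peptides are available (`sampling_rate`), and a
#' fraction of all points are false matches scattered uniformly over the data
#' range (`noise_fraction`, the FDR-style noise level: noise count is
#' `round(noise_fraction / (1 - noise_fraction) * n_signal)` so that noise
#' makes up `noise_fraction` of the total). Noise x and y are drawn
#' independently and uniformly over the sampled-signal range; with
#' `noise_x_limit_factor > 1` the upper noise x limit extends to
#' `factor * max(signal x)` (out-of-range noise scenario), the lower limit is
#' unchanged.
#'
#' @param points Ground-truth [calibration_points] (e.g. [generate_curve()]).
#' @param sampling_rate Fraction of points kept as signal, in (0, 1].
#' @param noise_fraction Fraction of the final point set that is noise, in
#'   `[0, 1)`.
#' @param noise_x_limit_factor Multiplier on the upper noise x limit,
#'   default 1 (in-range noise).
#' @param seed Integer seed.
#'
#' @return A [calibration_points] object with attribute `is_signal` (logical,
#'   `TRUE` for sampled signal rows, `FALSE` for injected noise rows).
#' @export
subsample_and_add_noise <- function(points, sampling_rate, noise_fraction,
                                    noise_x_limit_factor = 1, seed = 1L) {
  stopifnot(sampling_rate > 0, sampling_rate <= 1,
            noise_fraction >= 0, noise_fraction < 1,
            noise_x_limit_factor >= 1)
  set.seed(as.integer(seed))
  n <- nrow(points)
  n_signal <- round(sampling_rate * n)
  if (n_signal < 1L) stop("degenerate scenario: no signal points sampled",
                          call. = FALSE)
  idx <- sample.int(n, n_signal)
  sx <- points$library_rt[idx]
  sy <- points$measured_rt[idx]
  n_noise <- round(noise_fraction / (1 - noise_fraction) * n_signal)
  if (n_noise > 0L) {
    nx <- stats::runif(n_noise, min(sx), noise_x_limit_factor * max(sx))
    ny <- stats::runif(n_noise, min(sy), max(sy))
    out <- calibration_points(c(sx, nx), c(sy, ny))
    attr(out, "is_signal") <- c(rep(TRUE, n_signal), rep(FALSE, n_noise))
  } else {
    out <- calibration_points(sx, sy)
    attr(out, "is_signal") <- rep(TRUE, n_signal)
  }
  out
}

#' Mean relative deviation on signal points
#'
#' Fitting-accuracy metric: the mean, over signal (non-noise) points only, of
#' the absolute difference between predicted and measured RT, normalized by
#' the measured-RT range of the signal points. Noise points never affect the
#' value.
#'
#' @param predicted_rt,measured_rt Numeric vectors of equal length.
#' @param is_signal Logical vector marking the true (non-noise) points.
#'
#' @return Non-negative scalar MRD.
#' @export
mrd <- function(predicted_rt, measured_rt, is_signal) {
  stopifnot(length(predicted_rt) == length(measured_rt),
            length(is_signal) == length(measured_rt))
  if (!any(is_signal)) stop("need at least one signal point", call. = FALSE)
  m <- measured_rt[is_signal]
  rng <- diff(range(m))
  if (rng <= 0) stop("zero measured-RT range among signal points",
                     call. = FALSE)
  mean(abs(predicted_rt[is_signal] - m)) / rng
}
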