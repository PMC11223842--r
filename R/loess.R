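#' Fit the calibration curve through path nodes
#'
#' Locally weighted regression (LOESS, degree 1, tricube weights, no
#' robustness iterations — noise has already been removed upstream) through a
#' set of support points, with linear extrapolation beyond both ends. Point
#' weights default to node frequencies, so a cell summarizing many raw points
#' pulls the curve harder. Duplicate x positions are collapsed to their
#' weight-averaged y before fitting. With fewer than three distinct x values
#' the curve degenerates to the straight line through the points.
#'
#' The smoothing fraction is floored so each local window contains at least
#' two support points. End slopes for extrapolation are secants through each
#' anchor and the knot nearest to 10% of the fitted x-range inside it, which
#' is robust to jitter in a single end knot.
#'
#' @param x,y Numeric vectors of support coordinates (library RT, measured RT).
#' @param w Positive weights, default 1 (use cell frequencies for path nodes).
#' @param frac LOESS smoothing fraction, default 0.3.
#' @param monotone If `TRUE`, apply a cumulative-maximum projection to the
#'   fitted knot values so the curve is non-decreasing. Off by default: the
#'   ascending-path constraint upstream already makes the support monotone.
#'
#' @return An object of class `rt_calibration`: fitted knots, end anchors and
#'   slopes, callable via [predict.rt_calibration()].
#' @export
fit_loess_curve <- function(x, y, w = rep(1, length(x)), frac = 0.3,
                            monotone = FALSE) {
  stopifnot(length(x) == length(y), length(w) == length(x), all(w > 0))
  ord <- order(x)
  x <- x[ord]; y <- y[ord]; w <- w[ord]
  # collapse duplicate x by weighted mean y (interpolation needs strict order)
  if (anyDuplicated(x)) {
    ux <- unique(x)
    grp <- factor(match(x, ux), levels = seq_along(ux))
    y <- as.numeric(tapply(y * w, grp, sum) / tapply(w, grp, sum))
    w <- as.numeric(tapply(w, grp, sum))
    x <- ux
  }
  n <- length(x)
  if (n < 2L) {
    stop("need at least 2 distinct x values to fit a curve", call. = FALSE)
  }
  if (n == 2L) {
    ky <- y
  } else {
    span_used <- min(1, max(frac, 3 / n))
    # collinear or near-duplicate support triggers benign "pseudoinverse"
    # warnings from the local solver; the fit is still exact there
    fit <- tryCatch(
      suppressWarnings(
        stats::loess(y ~ x, weights = w, span = span_used, degree = 1,
                     family = "gaussian",
                     control = stats::loess.control(surface = "direct"))),
      error = function(e) NULL
    )
    ky <- if (is.null(fit)) {
      # degenerate support for local regression: weighted straight line
      lf <- stats::lm(y ~ x, weights = w)
      as.numeric(stats::predict(lf, data.frame(x = x)))
    } else {
      as.numeric(suppressWarnings(stats::predict(fit, data.frame(x = x))))
    }
  }
  if (monotone) ky <- cummax(ky)
  new_rt_calibration(knots_x = x, knots_y = ky, loess_frac = frac)
}

# build the model object from knots; slopes/anchors derived from the knots
new_rt_calibration <- function(knots_x, knots_y, loess_frac,
                               fallback = FALSE, meta = list()) {
  n <- length(knots_x)
  if (n == 1L) {
    left_slope <- right_slope <- 0
  } else {
    xr <- knots_x[n] - knots_x[1]
    sl <- function(anchor, target_x, exclude) {
      i <- which.min(abs(knots_x - target_x))
      if (i == exclude) i <- i + if (exclude == 1L) 1L else -1L
      (knots_y[i] - knots_y[exclude]) / (knots_x[i] - knots_x[exclude])
    }
    left_slope <- sl(1L, knots_x[1] + 0.10 * xr, 1L)
    right_slope <- sl(n, knots_x[n] - 0.10 * xr, n)
  }
  structure(
    list(knots_x = knots_x, knots_y = knots_y,
         left_anchor = c(x = knots_x[1], y = knots_y[1]),
         right_anchor = c(x = knots_x[n], y = knots_y[n]),
         left_slope = left_slope, right_slope = right_slope,
         loess_frac = loess_frac, fallback = fallback, meta = meta),
    class = "rt_calibration"
  )
}

#' Predict measured RTs from a calibration model
#'
#' Inside the fitted region the curve is the linear interpolation of the LOESS
#' knot values; beyond either anchor the prediction continues linearly with
#' the model's end slope, passing exactly through the anchor (so the curve is
#' continuous everywhere and exactly linear outside the fitted range).
#'
#' @param object An `rt_calibration` model.
#' @param newdata Numeric vector of library RT/iRT values.
#' @param ... Ignored.
#'
#' @return Numeric vector of predicted measured RTs, same length as `newdata`.
#' @export
predict.rt_calibration <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  if (length(x) == 0L) return(numeric(0))
  kx <- object$knots_x; ky <- object$knots_y
  if (length(kx) == 1L) {
    out <- rep(ky, length(x))
  } else {
    out <- stats::approx(kx, ky, xout = x, rule = 2)$y
  }
  lo <- x < object$left_anchor["x"]
  hi <- x > object$right_anchor["x"]
  out[lo] <- object$left_anchor["y"] +
    object$left_slope * (x[lo] - object$left_anchor["x"])
  out[hi] <- object$right_anchor["y"] +
    object$right_slope * (x[hi] - object$right_anchor["x"])
  out
}

#' @export
print.rt_calibration <- function(x, ...) {
  cat(sprintf(
    "<rt_calibration> %d knot(s) on [%.4g, %.4g]%s\n",
    length(x$knots_x), x$left_anchor["x"], x$right_anchor["x"],
    if (isTRUE(x$fallback)) " (linear fallback)" else ""))
  cat(sprintf("  end slopes: left %.4g, right %.4g\n",
              x$left_slope, x$right_slope))
  invisible(x)
}

#' Serialize a calibration model to JSON
#'
#' @param model An `rt_calibration` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rt_model <- function(model, path) {
  obj <- unclass(model)
  obj$left_anchor <- as.list(obj$left_anchor)
  obj$right_anchor <- as.list(obj$right_anchor)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path Path to a file written by [write_rt_model()].
#' @return An `rt_calibration` model.
#' @export
read_rt_model <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("model file not found: %s", path), call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("knots_x", "knots_y", "left_slope", "right_slope")) {
    if (is.null(obj[[f]]) || !is.numeric(obj[[f]])) {
      stop("malformed model file: missing or non-numeric field ", f,
           call. = FALSE)
    }
  }
  obj$left_anchor <- unlist(obj$left_anchor)
  obj$right_anchor <- unlist(obj$right_anchor)
  class(obj) <- "rt_calibration"
  obj
}
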