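#' Paired calibration points
#'
#' Container for paired (library RT/iRT, measured RT) observations, one row per
#' precursor/peptide. Library RT is on the spectral-library scale (dimensionless
#' iRT or minutes); measured RT is on the scale of the current run (minutes).
#'
#' @param library_rt Numeric vector of library RT/iRT values.
#' @param measured_rt Numeric vector of measured RT values (minutes).
#'
#' @return A data frame of class `calibration_points` with columns
#'   `library_rt` and `measured_rt`; all rows are finite.
#' @export
#'
#' @examples
#' calibration_points(c(10, 20), c(5.1, 9.8))
calibration_points <- function(library_rt, measured_rt) {
  library_rt <- as.numeric(library_rt)
  measured_rt <- as.numeric(measured_rt)
  if (length(library_rt) != length(measured_rt)) {
    stop("library_rt and measured_rt must have equal length", call. = FALSE)
  }
  if (length(library_rt) < 1L) {
    stop("at least one calibration pair is required", call. = FALSE)
  }
  if (!all(is.finite(library_rt)) || !all(is.finite(measured_rt))) {
    stop("calibration points must be finite; filter before construction",
         call. = FALSE)
  }
  structure(
    data.frame(library_rt = library_rt, measured_rt = measured_rt),
    class = c("calibration_points", "data.frame")
  )
}

#' @export
print.calibration_points <- function(x, ...) {
  cat(sprintf("<calibration_points> %d pairs\n", nrow(x)))
  cat(sprintf("  library_rt:  [%.4g, %.4g]\n",
              min(x$library_rt), max(x$library_rt)))
  cat(sprintf("  measured_rt: [%.4g, %.4g]\n",
              min(x$measured_rt), max(x$measured_rt)))
  invisible(x)
}

#' Read paired RT values from a delimited table
#'
#' Reads a TSV/CSV file with a header row and extracts the library and measured
#' RT columns. Rows where either value is missing or non-finite are dropped and
#' their count reported via [message()].
#'
#' @param path Path to the input file.
#' @param library_column,measured_column Column names holding the library RT
#'   (or iRT) and the measured RT. Defaults `"library_rt"`, `"measured_rt"`.
#' @param delimiter Field delimiter, default tab.
#'
#' @return A [calibration_points] object with all finite pairs in file order.
#' @export
read_rt_pairs <- function(path,
                          library_column = "library_rt",
                          measured_column = "measured_rt",
                          delimiter = "\t") {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "NaN", ""))
  for (col in c(library_column, measured_column)) {
    if (!col %in% names(tab)) {
      stop(sprintf("column '%s' not found; available columns: %s",
                   col, paste(names(tab), collapse = ", ")), call. = FALSE)
    }
  }
  x <- suppressWarnings(as.numeric(tab[[library_column]]))
  y <- suppressWarnings(as.numeric(tab[[measured_column]]))
  keep <- is.finite(x) & is.finite(y)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("read_rt_pairs: dropped %d non-finite/malformed row(s)",
                    dropped))
  }
  if (!any(keep)) {
    stop("no valid calibration pairs in input", call. = FALSE)
  }
  calibration_points(x[keep], y[keep])
}

#' Write predicted RTs to a TSV file
#'
#' @param path Output path.
#' @param library_rt Numeric vector of library RT values.
#' @param predicted_rt Numeric vector of predicted measured RTs, same length.
#'
#' @return Number of data rows written (invisibly usable as a check).
#' @export
write_rt_predictions <- function(path, library_rt, predicted_rt) {
  if (length(library_rt) != length(predicted_rt)) {
    stop("library_rt and predicted_rt must have equal length", call. = FALSE)
  }
  tab <- data.frame(library_rt = library_rt, predicted_rt = predicted_rt)
  # 15 significant digits so write -> read round-trips to ~1e-9 and better
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  nrow(tab)
}
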