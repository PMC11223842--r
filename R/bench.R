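#' Run the synthetic calibration benchmark matrix
#'
#' Full factorial over curve archetypes, sampling rates, noise fractions,
#' methods, and seeded replicates. For each scenario a ground-truth curve is
#' generated, subsampled, and contaminated with uniform noise; each method is
#' fitted on the same contaminated data and scored by [mrd()] on the signal
#' points.
#'
#' @param curve_types Character vector of archetypes (see [generate_curve()]).
#' @param sampling_rates Numeric vector of sampling rates in (0, 1].
#' @param noise_fractions Numeric vector of noise fractions in `[0, 1)`.
#' @param methods Methods to score: `"rtcalib"` (the grid-and-path pipeline)
#'   and/or the [baseline_fit()] methods.
#' @param n_seeds Number of replicates per scenario.
#' @param n_truth Ground-truth points per curve (default 2500).
#' @param noise_x_limit_factor Upper noise x limit multiplier (default 1).
#' @param grid_size,span_filter,span_threshold,loess_frac Passed to
#'   [fit_calibration()] for the `"rtcalib"` method; `loess_frac` is shared
#'   with the baselines.
#' @param base_seed Base of the replicate seed stream.
#' @param out_tsv Optional path: write the tidy result table as TSV.
#'
#' @return A data frame with columns `method`, `curve_type`, `sampling_rate`,
#'   `noise_fraction`, `seed`, `mrd` (one row per method x scenario x seed).
#' @export
run_experiment_matrix <- function(curve_types = c("linear", "distortion_begin",
                                                  "distortion_end",
                                                  "exponential", "s_type"),
                                  sampling_rates = c(0.01, 0.1, 0.3, 0.5),
                                  noise_fractions = c(0.01, 0.05, 0.35, 0.75),
                                  methods = c("rtcalib", "raw_loess",
                                              "quantile_loess",
                                              "ransac_loess"),
                                  n_seeds = 1L,
                                  n_truth = 2500L,
                                  noise_x_limit_factor = 1,
                                  grid_size = 100L,
                                  span_filter = FALSE,
                                  span_threshold = 0.10,
                                  loess_frac = 0.3,
                                  base_seed = 1L,
                                  out_tsv = NULL) {
  rows <- list()
  for (ct in curve_types) {
    for (sr in sampling_rates) {
      for (nf in noise_fractions) {
        for (k in seq_len(n_seeds)) {
          gen_seed <- base_seed + 1000L * k
          noise_seed <- base_seed + 1000L * k + 1L
          truth <- generate_curve(ct, n = n_truth, seed = gen_seed)
          scen <- subsample_and_add_noise(
            truth, sampling_rate = sr, noise_fraction = nf,
            noise_x_limit_factor = noise_x_limit_factor, seed = noise_seed)
          sig <- attr(scen, "is_signal")
          for (m in methods) {
            model <- if (m == "rtcalib") {
              suppressWarnings(fit_calibration(
                scen, grid_size = grid_size, span_filter = span_filter,
                span_threshold = span_threshold, loess_frac = loess_frac))
            } else {
              baseline_fit(m, scen, loess_frac = loess_frac,
                           seed = noise_seed)
            }
            pred <- predict(model, scen$library_rt)
            rows[[length(rows) + 1L]] <- data.frame(
              method = m, curve_type = ct, sampling_rate = sr,
              noise_fraction = nf, seed = k,
              mrd = mrd(pred, scen$measured_rt, sig))
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(method = character(0), curve_type = character(0),
               sampling_rate = numeric(0), noise_fraction = numeric(0),
               seed = integer(0), mrd = numeric(0))
  if (!is.null(out_tsv)) {
    utils::write.table(out, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Median MRD per benchmark cell
#'
#' Collapses the tidy replicate table from [run_experiment_matrix()] to the
#' median MRD per (method, curve type, sampling rate, noise fraction) cell.
#'
#' @param results Data frame from [run_experiment_matrix()].
#' @return Data frame with one row per cell and a `median_mrd` column.
#' @export
summarize_experiment <- function(results) {
  agg <- stats::aggregate(
    mrd ~ method + curve_type + sampling_rate + noise_fraction,
    data = results, FUN = stats::median)
  names(agg)[names(agg) == "mrd"] <- "median_mrd"
  agg[order(agg$curve_type, agg$sampling_rate, agg$noise_fraction,
            agg$method), , drop = FALSE]
}
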