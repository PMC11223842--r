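# rtcalib

Noise-tolerant, monotonicity-aware retention-time (RT) calibration for DIA
mass-spectrometry proteomics.

DIA identification engines score candidate peptide-spectrum matches partly by
how far a peptide's measured RT falls from its estimated RT. The estimate
comes from the spectral library, whose RT/iRT scale differs from the
chromatographic scale of the current run, so a calibration curve mapping
library RT/iRT to measured RT must be fitted first — from calibration pairs
that are themselves contaminated by false matches. Depending on how the
engine selects those pairs, the fraction of noise points can reach 75% of the
input, while the true relationship is a monotone, often nonlinear curve that
is dense mid-gradient and sparse at the ends. `rtcalib` fits that curve
robustly and deterministically, at a cost independent of the number of input
pairs.

## Method

Given `n` pairs `(x_i, y_i)` of library RT/iRT and measured RT:

1. **Grid and count.** The plane is gridded (default 100×100 equal-width
   cells over the data range) and per-cell frequencies counted.
2. **Non-maximal suppression.** In every grid row and every grid column only
   the highest-count cell is kept, so at most `2 × grid_size` cells survive,
   whatever `n` is. Each retained cell is represented by the mean of its
   member points and carries its count as a frequency.
3. **Maximum-weight ascending path.** Retained cells become nodes of a DAG
   with an edge `u → v` whenever `v` is not smaller than `u` in both grid
   dimensions, weighted `freq(u)·freq(v) / dist(u, v)` (Euclidean distance in
   grid-index units). Dynamic programming extracts the path with the maximum
   weight sum: chains of nearby, high-frequency cells — the signal ridge —
   dominate scattered noise, and the path is monotone by construction.
4. **Span filter (optional, off by default).** End nodes whose gap to their
   inner neighbour exceeds 10% of the full range in either dimension are
   trimmed; useful when noise extends beyond the true library-RT range.
5. **LOESS and linear extrapolation.** A frequency-weighted LOESS (degree 1,
   tricube) through the surviving nodes gives the curve inside the fitted
   range; beyond both ends the curve continues linearly through the end
   anchors.

The fitted model is a callable `library RT/iRT → estimated measured RT`
mapping. A synthetic benchmark module generates the five monotone curve
archetypes seen in practice (linear, distortion at the beginning/end of
elution, exponential, S-type), subsamples them, injects uniform FDR-style
noise, and scores any calibrator by the mean relative deviation
`MRD = mean(|predicted − measured|) / range(measured)` over the true
(non-noise) points. Three generic baselines (Raw-LOESS, Quantile-LOESS,
RANSAC-LOESS) are included for comparison.

## Worked example

```r
library(rtcalib)

truth <- generate_curve("s_type", n = 2500, seed = 1)        # ground truth
scen  <- subsample_and_add_noise(truth, sampling_rate = 0.1,  # 250 signal
                                 noise_fraction = 0.75,       # +750 noise
                                 seed = 2)
model <- fit_calibration(scen, verbose = TRUE)
#> fit_calibration: 1000 points -> 156 retained cells -> 75 path nodes -> 75 after span filter

predict(model, c(10, 50, 90))
#> [1]  12.73669  70.02684 128.33519

mrd(predict(model, scen$library_rt), scen$measured_rt, attr(scen, "is_signal"))
#> [1] 0.008476328
```

Despite 75% of the points being uniform noise, the fitted curve deviates from
the measured RTs of the true points by under 1% of the elution range. The same
model object serializes to JSON (`write_rt_model()`) and powers the
command-line interface (`inst/cli/rtcalib fit | transform | bench`).

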