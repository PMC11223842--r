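Package: rtcalib
Title: Noise-Tolerant Monotone Retention Time Calibration for DIA Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Calibrates spectral-library retention times (RT/iRT) onto the
    measured RT scale of a DIA mass-spectrometry run. The point cloud of
    (library RT, measured RT) pairs is gridded, thinned by row/column
    non-maximal suppression, and the maximum-weight ascending path through the
    retained cells is extracted by dynamic programming; a frequency-weighted
    LOESS through the path nodes, with linear extrapolation beyond both ends,
    yields a callable calibration curve that tolerates high fractions of
    false-match noise. Includes a synthetic benchmark suite (five monotone
    curve archetypes, subsampling, uniform noise injection, mean relative
    deviation metric) and three baseline calibrators for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
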