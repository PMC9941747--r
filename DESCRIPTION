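Package: ramanpipe
Title: Preprocessing, Baseline Removal and Benchmarking for Raman Spectra
Version: 1.0.0
Authors@R:
    person("ramanpipe", "developers", email = "ramanpipe@example.org",
           role = c("aut", "cre"))
Description: Tools for turning raw Raman spectroscopy acquisitions into
    analysis-ready spectra: truncation of the filter-transition region,
    cosmic-ray spike removal (single-spectrum and cross-accumulation),
    background subtraction with exposure-time normalization, instrument
    response (y-axis) correction against a standard reference material,
    Raman-shift (x-axis) calibration from reference-sample peaks, and
    three baseline-removal algorithms centered on the BubbleFill
    morphological method. Includes spectral quality metrics (SNV, RBR,
    ASSI with quality tiering) and a synthetic-spectrum benchmark
    framework that scores baseline algorithms by normalized mean squared
    error over signal-to-baseline-ratio sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
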