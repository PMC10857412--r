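Package: madpair
Title: Paired-Device Validation of Accelerometer Activity Intensity via
    Mean Amplitude Deviation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating a chest-worn ECG patch's low-rate
    accelerometer against a hip-worn research accelerometer. Decodes the
    patch's 8-bit interleaved binary accelerometer dialect and raw
    tri-axial CSV exports, summarises vector-magnitude acceleration as
    mean amplitude deviation (MAD) over fixed epochs, detects non-wear
    per device (an ECG deviation rule for the chest patch, a 90-minute
    zero-activity run rule for the hip monitor), applies wear-validity
    inclusion filtering, and computes multi-level agreement statistics
    (participant-level Pearson correlation and mean squared error,
    Bland-Altman limits of agreement, diurnal profiles). Includes a
    synthetic paired-device cohort simulator with known ground truth so
    the full pipeline is testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
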