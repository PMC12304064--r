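Package: qtsnap
Title: Marker-Based QT and QTc Measurement from ECG Monitor Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Semi-automated measurement of the QT interval from a raster
    snapshot of a single-lead ECG trace as displayed on a patient monitor
    (or a 25 mm/s paper printout). Three fiducial markers - two neighboring
    Q-wave onsets and the T-wave end between them - together with the
    displayed heart rate calibrate the pixel-to-time scale; QT is corrected
    to QTc with Bazett's formula. Includes a synthetic single-lead ECG
    snapshot generator with exact ground-truth fiducials, a column-wise
    trace digitizer for round-trip validation, the full Bland-Altman method
    comparison analysis (bias, limits of agreement with confidence
    intervals, agreement grading, Pearson correlation, clinical
    acceptability), and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    ggplot2,
    optparse,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
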