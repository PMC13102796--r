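Package: fillfrac
Title: Filling Fraction and Single-Beat Estimation of Left-Ventricular
    Dead-Space Volume
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-beat estimation of the left-ventricular dead-space
    (absolute minimum) volume from end-diastolic and end-systolic
    echocardiographic measurements, via a linear end-systolic stress-stretch
    law and a cubic volume-perimeter extrapolation; the derived preload
    metric filling fraction and the three-factor decomposition of ejection
    fraction into preload, contractility and afterload; and a truncated
    prolate-ellipsoid synthetic-heart generator for in-silico verification
    of the estimator over large randomly sampled cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
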