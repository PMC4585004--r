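Package: locfuse
Title: Two-Dimensional Visual-Auditory Localization Fields and Maximum-Likelihood Cue Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of two-dimensional open-loop localization of visual,
    auditory, and bimodal targets: per-target bivariate response
    distributions and their confidence-ellipse geometry (precision),
    constant-error vector fields and global affine distortion maps
    (accuracy), maximum-likelihood fusion of unimodal distributions into
    predicted bimodal performance, and multisensory integration metrics
    (redundancy gain, inverse effectiveness, weight-accuracy relations).
    Includes a calibrated synthetic generator of trial-level pointing data
    with modality-specific bias and covariance fields, an end-to-end
    pipeline producing summary tables and field plots, and a numerical
    quadrature oracle for the fusion algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
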