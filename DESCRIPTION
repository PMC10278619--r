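Package: veinpulse
Title: Cardiac-Gated Timing of Retinal Vein Pulsation from Synchronized
    Fundus Video and Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic measurement of spontaneous retinal vein
    pulsation timing from video-ophthalmoscope recordings synchronized with
    an electrocardiogram. Detects ECG R-waves with an adaptive filtered
    peak detector, locates camera trigger edges to place every video frame
    on the biosignal timeline, flags distorted (blink or blurred) frames by
    a local-median-image distance combined with Rosner's generalized
    extreme Studentized deviate test, converts the vein region-of-interest
    intensity into a photoplethysmographic representation, and measures the
    per-cycle time from the R-wave to vein collapse. A synthetic-data
    module emulates the whole acquisition chain (ECG, frame trigger, fundus
    video with a pulsating vein) with known ground truth so every stage can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
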