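Package: eyeforge
Title: Parametric Synthetic Eye Images for Training Gaze-Feature Localizers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Light-weight parametric generators of abstract synthetic eye images
    (pupils, corneal reflections, iris, sclera and collarette structures,
    illuminator constellations) for training pupil and corneal-reflection
    localization models, together with the post-processing used at inference
    time (heatmap peak extraction, best-two corneal-reflection selection,
    adaptive pupil-prior cutouts), a classical thresholding baseline,
    eye-tracking data-quality metrics (windowed RMS-S2S and STD precision,
    accuracy, cumulative detection rate) with polynomial P-CR gaze calibration,
    and a desk-scale convolutional-network training harness that demonstrates
    sub-pixel feature localization on streamed synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    withr,
    png,
    yaml,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
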