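Package: neurogaze
Title: Model-Independent Neural Eye-Gaze Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: A pupil-centre corneal-reflection (PCCR) gaze-tracking pipeline
    that maps infrared eye-image features to on-screen point of gaze without
    any geometric model of the eye or the apparatus. The package renders
    synthetic dark-pupil eye frames with a triangular three-glint pattern,
    detects the pupil centre by a circle Hough transform and the glints by
    thresholding, connected-component labelling and subpixel centroiding
    with geometric validation of the glint triangle, and learns the mapping
    from the eight extracted image coordinates to screen coordinates with
    two single-output feed-forward neural networks trained by batch
    backpropagation. Calibration and test sessions follow a fixed
    grid-and-dwell protocol, and accuracy is reported as root-mean-square
    error in pixels and degrees of visual angle. A linear-regression
    baseline is included for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
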