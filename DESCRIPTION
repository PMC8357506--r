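Package: echotrack
Title: Speckle Tracking for Echocardiographic Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks feature points through echocardiographic (cardiac
    ultrasound) image sequences. Implements a SIFT-style keypoint detector
    and 128-dimensional descriptor, ratio-test feature matching with a K-D
    tree and Best-Bin-First search, a weighted iterative Lucas-Kanade
    optical-flow refinement run coarse-to-fine over an image pyramid, and a
    tolerance-gated tracking loop that emits per-point, per-frame trajectory
    tables with an explicit lost state. Includes a synthetic speckle-phantom
    generator with known ground-truth motion (translation, rotation,
    periodic radial contraction) and configurable noise so that every stage
    is testable without clinical recordings, plus a linear mean filter for
    despeckling frames before feature extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
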