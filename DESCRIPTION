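Package: cellmot
Title: Cell Detection-Tracking with Lightweight Attention Blocks, Two-Round
    IoU Association, and Multi-Object Tracking Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking-by-detection analysis of time-lapse microscopy:
    lightweight neural building blocks (efficient multi-scale attention, its
    inverted-residual wrapper, and group-shuffle convolution) with exact
    parameter accounting against a nano-scale one-stage detector topology; a
    BoT-SORT-style multi-object tracker with Kalman prediction/update, optional
    camera-motion compensation, two-round confidence-gated IoU association and
    tracklet lifecycle management; CLEAR-MOT, identity and HOTA evaluation
    metrics with MOTChallenge-format readers and writers; and a seeded
    generator of synthetic cell sequences (division, boundary exit, detector
    corruption, rendered frames) so the full pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
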