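Package: ethotrack
Title: Video Tracking, Behavior Classification and Closed-Loop Stimulus
    Simulation for Tube-Housed Flies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A desk-scale re-implementation of the software core of a
    machine-vision platform for high-throughput fly ethomics: fiducial-based
    registration of tube regions of interest, adaptive
    background-subtraction tracking of one fly per tube, three-state
    behavior classification (immobile, micromovement, walking) from
    frame-interval-corrected maximal velocity, a combinatorial
    position/time/behavior trigger engine with post-stimulus masking for
    closed-loop experiments, and sleep-bout analysis with bootstrap
    confidence bands and rank-based statistics. A built-in synthetic arena
    generator renders grayscale frame sequences with exact ground truth, so
    the whole pipeline is testable end to end without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
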