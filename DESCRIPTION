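Package: exomoment
Title: EMG-Driven Lumbar Moment Estimation and Calibration-Set
    Optimization for Back-Support Exoskeleton Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the moment about the lumbosacral
    (L5/S1) joint during manual material handling and for optimizing
    the calibration procedure of a reduced-sensor prediction model
    intended for back-support exoskeleton control.  Implements a planar
    bottom-up inverse dynamics model, an EMG-driven Hill-type trunk
    muscle model with seven subject-specific parameters calibrated by
    bounded least squares, and a Gaussian-kernel support-vector
    regression that predicts the actively generated moment from four
    back-muscle EMG channels and five exoskeleton-measurable kinematic
    signals.  A synthetic lifting-trial generator with known
    ground-truth muscle parameters reproduces the full study design
    (fourteen calibration lift conditions plus exoskeleton-assisted
    lifting, box stacking, shelf lifting, and push/pull test tasks) so
    the entire pipeline, including the enumeration and evaluation of
    calibration-trial subsets, can be run and tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    lhs,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
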