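Package: vestgait
Title: Gait-Cycle Deep Learning Classification of Vestibular Deficit from
    Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying vestibular-deficit gait from
    multi-sensor wearable inertial measurement unit (IMU) recordings. Detects
    gait cycles from right-ankle pitch angular velocity, resamples each cycle
    to a fixed 6 x 512 matrix, and classifies cycles with a six-branch
    parallel one-dimensional convolutional neural network trained with
    binary cross-entropy and an adaptive-moment optimizer. Evaluation uses
    paired subject-level leave-one-out cross-validation with train-range
    normalization, and the package ships drivers for sensor-placement sweeps,
    transfer learning with frozen convolutional stages, and subject/sample
    ablation experiments. A synthetic quasi-periodic gait cohort generator
    and an activity-window generator make every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
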