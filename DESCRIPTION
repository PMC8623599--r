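Package: ambustride
Title: Classification of Dependent Ambulation from Walking-Video Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for classifying dependent versus independent ambulation of
    stroke patients from walking video analysed as 2D pose keypoints. Provides
    OpenPose-style keypoint input/output, SORT-style multi-person tracking with a
    keypoint-adapted association model, patient-centered clip extraction, a small
    3D convolutional video classifier trained with a cyclic SGD schedule,
    keypoint-based swing-time asymmetry measurement, an uncertainty-band fusion
    rule combining the two, fivefold cross-validated evaluation, and a synthetic
    gait simulator with fully known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
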