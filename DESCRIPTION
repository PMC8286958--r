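Package: carmpose
Title: Two-Stage Pose Regression for Automatic C-Arm Positioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and learning framework for automatic positioning of a
    mobile C-arm toward anatomy-specific standard fluoroscopic projections.
    Provides a 5 degree-of-freedom C-arm pose model with beam-direction and
    pose-error metrics, a parametric bone-phantom generator with per-subject
    reference standard poses, a ray-casting line-integral projector producing
    digitally reconstructed radiographs, coarse and fine pose-sampling and
    augmentation pipelines, convolutional pose regressors trained with
    weighted L2 (sin/cos in-plane rotation) and weighted L1 losses, and an
    evaluation harness for two-stage iterative pose correction with
    single-stage and iterated-coarse baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
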