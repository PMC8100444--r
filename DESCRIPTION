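Package: stickgen
Title: Synthetic Video Generation and Evaluation for Marker-Less Insect Pose Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic top-view videos of a walking stick insect
    with automatic 22-keypoint ground-truth annotation, for training and
    benchmarking marker-less pose estimators. Builds 3D postures from
    joint-angle time courses by forward kinematics over a cylinder/sphere
    body model, renders them through a pinhole camera with analytic
    ray-casting, applies controlled translation/rotation/scaling
    augmentation, exports DeepLabCut-compatible annotations, and scores
    keypoint predictions with confidence-based exclusion plus the
    associated non-parametric statistical battery (Friedman, Wilcoxon
    matched pairs, Mann-Whitney rank sums).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    stats,
    yaml,
    png,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
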