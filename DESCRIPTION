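Package: lungcad
Title: Lung Nodule Computer-Aided Detection with Multiscale Dense 3D U-Nets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable toolkit for pulmonary-nodule computer-aided detection
    on thoracic CT. Provides MetaImage (.mhd/.raw) volume input/output with
    isotropic resampling and intensity standardization; seeded synthetic thorax
    phantoms with ground-truth lung, airway and nodule masks; a four-step lung
    parenchyma segmentation pipeline (adaptive thresholding, background removal,
    optimal-threshold trachea growing, grayscale closing-by-reconstruction for
    bronchi, integral-projection lung separation, rolling-ball boundary repair);
    a configuration-driven builder, shape tracer and CPU training engine for a
    multiscale 3D U-Net with dense blocks and dilated convolutions, including
    Adam/SGD optimization, six-fold data augmentation and transfer-learning
    layer freezing; and FROC-based detection evaluation with size-stratified
    reporting and k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
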