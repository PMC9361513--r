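Package: convatt
Title: Multi-Input Convolutional Self-Attention Models for Drawing-Based
    Cognitive Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification of mild cognitive impairment from triplets of
    drawing-task images (clock drawing, cube copying, trail making) with a
    multi-input convolutional network aggregated by CLS-token self-attention
    instead of global pooling.  Supports soft diagnostic labels derived from
    Montreal Cognitive Assessment scores, attention-rollout and Grad-CAM
    heat maps, ROI-based interpretability scoring via intersection over
    union, stratified splitting and repeated-split evaluation, and a fully
    synthetic drawing generator with ground-truth anomaly masks so the whole
    pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    graphics,
    jsonlite,
    mgcv,
    png,
    rlang,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
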