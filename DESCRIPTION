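Package: fgcnn
Title: Feature-Guided Convolutional Networks for Continuous Knee-Angle
    Estimation from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates continuous knee-joint angles from single-channel
    surface electromyography (sEMG) recorded during level walking. Implements
    a feature-guided one-dimensional convolutional network (FG-CNN) in which a
    bank of 14 handcrafted time-domain features enters a tanh fusion layer to
    guide convolutional feature learning; the fused 28-dimensional feature
    vectors feed downstream regressors (random forest, gradient-boosted trees,
    multilayer perceptron, support vector regression, k-nearest neighbours).
    Includes zero-phase band-pass preprocessing, overlapping-window
    segmentation, angle-target alignment and scaling, NRMSE/correlation
    evaluation with trial-level cross-validation and Kruskal-Wallis method
    comparison, and a synthetic gait sEMG/kinematics generator so the whole
    pipeline is testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal,
    ranger,
    xgboost,
    e1071,
    nnet,
    caret,
    jsonlite,
    yaml,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'evaluation.R'
    'signal_io.R'
    'synthetic_gait.R'
    'regression.R'
    'features.R'
    'fgcnn.R'
    'experiment.R'
    'fgcnn-package.R'
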