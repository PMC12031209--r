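Package: mrcanet
Title: Multi-Task Residual Network with Channel Attention for Electronic-Nose
    Binary Gas Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simultaneous identification and concentration prediction of binary
    volatile-organic-compound mixtures (ethanol / n-propanol) from metal-oxide
    gas-sensor-array time series. Provides a synthetic sensor-array campaign
    generator with first-order response dynamics, peak-driven response
    segmentation with maximum-variation-rate window featurization, a multi-task
    residual convolutional network with squeeze-excitation-style channel
    attention and cross-stitch-style task fusion trained under a learnable
    homoscedastic-uncertainty weighted loss, and grouped 5-fold cross-validation
    with a full metric suite and ablation toggles.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    pROC,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
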