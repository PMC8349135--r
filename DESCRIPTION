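Package: ThermoInception
Title: Inception Network Builders and Diagnostic Evaluation for Breast
    Thermography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying deep convolutional classifiers of breast
    thermograms at desk scale. Builds the inception V3 and V4 architectures
    and a modified V4 (MV4) with a shallower inception-B block that preserves
    its 1024 concatenated feature channels, as explicit layer graphs with
    shape inference, parameter counting and FLOP estimation. Includes the
    twelve-metric diagnostic evaluation suite (sensitivity, specificity,
    likelihood ratios, balanced-accuracy AUC, equal error rate, F1) with
    explicit undefined-value semantics, thermal-image reading, grayscale
    conversion, resizing and seeded augmentation, a synthetic thermogram
    simulator (bilaterally symmetric healthy fields versus asymmetric
    hot-spot pathology), and a reproducible training/evaluation harness with
    SGDM, Adam and RMSprop optimizers over width-scaled network variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    png,
    tiff,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
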