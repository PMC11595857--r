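Package: esaresnet
Title: Lightweight Attention Residual Networks for Crop Pest and Disease
    Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and audits ESA-ResNet34, a lightweight
    convolutional classifier for crop pest and disease images that combines
    a ResNet34 backbone with an effective spatial attention (ESA) channel
    gate and depthwise-separable convolutions.  Includes a declarative
    architecture description for the network and the usual reference
    architectures (AlexNet, VGG16, DenseNet121, the ResNet family,
    MobileNetV2), an exact parameter and multiply-accumulate profiler with
    per-layer breakdown, a seeded training harness (Adam, plateau learning
    rate schedule, early stopping), macro-averaged multiclass evaluation
    metrics, dataset readers for JSON-annotated and directory-per-class
    image collections, and a deterministic synthetic lesion-image generator
    so the whole pipeline is testable without any real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
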