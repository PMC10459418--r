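Package: tsidl
Title: Two-Stage Induced Deep Learning for Confusable Image Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for coarse-to-fine classification of visually confusable
    image classes, motivated by medication-dispensing safety: a stage-one
    classifier whose cross-validated confusion matrix drives an explicit
    similar-class grouping algorithm, per-group centered region-of-interest
    crops chosen from a halving pyramid, per-group stage-two classifiers,
    and a consolidated two-stage inference path. Includes confusion-matrix
    construction, fold aggregation and hierarchical projection with
    macro-averaged metrics, declarative convolutional architecture
    specifications with exact shape inference, a trainable momentum-SGD
    multilayer-perceptron backbone for desk-scale experiments, and a
    synthetic image generator that plants similarity groups of classes
    differing only in a small low-contrast central imprint, so the whole
    pipeline is testable without any external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
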