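Package: ngolc
Title: Northern Goshawk Optimization with Levy Flight and Chaos for
    GRU-Based Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the Northern Goshawk Optimization metaheuristic and
    its Levy-flight/chaos-map variant (NGO-LC), a suite of twelve analytic
    benchmark objectives for validating population optimizers, and a
    derivative-free neuroevolution pipeline in which the full weight vector
    of a gated recurrent unit (GRU) binary image classifier is trained by
    NGO-LC under a mean-squared-error fitness. Ships the surrounding
    pipeline for two-class medical image collections: random oversampling
    for class imbalance, a seven-operator image augmentation stack,
    standardizing resize, stratified train/test splitting,
    confusion-matrix metrics, and a seeded synthetic two-class image
    generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
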