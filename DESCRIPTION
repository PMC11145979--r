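Package: gppwvgg
Title: Lightweight Partial-Convolution VGG Networks for Crop-Variety Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds, budgets and trains the G-PPW-VGG11 family of lightweight
    convolutional networks for field crop-variety (wheat canopy) image
    classification. Provides the family's building-block operators (partial
    convolution, partially-mixed multi-kernel convolution, efficient channel
    attention with the adaptive odd-kernel rule, and a pointwise-convolution
    plus global-average-pooling classifier head), a declarative architecture
    builder for the baseline, reduced and ablation presets, exact parameter
    and multiply-accumulate accounting that reproduces the family's published
    model budgets, the accompanying augmentation/splitting data protocol, a
    seeded synthetic canopy-image generator, and a CPU training/evaluation
    harness with confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
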