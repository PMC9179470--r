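Package: sparrowtex
Title: Chaotic Sparrow Search Tuned Texture Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for multi-class texture image
    classification built from four interoperating stages: a Gabor filter
    bank for noise-suppressing preprocessing, a mixed-depthwise-convolution
    (MDConv) feature extractor with parameter and FLOP accounting for
    depthwise-separable convolutions, a stacked gated recurrent unit (GRU)
    classification head trained by mini-batch gradient descent, and a
    chaotic sparrow search optimizer (logistic-map local search with
    linear shrink blending) that tunes the classifier hyperparameters by
    minimizing validation error rate. Includes a deterministic synthetic
    generator for an eight-class benign/malignant-style texture dataset,
    one-vs-rest confusion-matrix metrics (accuracy, precision, recall,
    specificity, F-score, MCC, G-mean) with macro averaging, broom-style
    tidiers and ggplot2 autoplot methods for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
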