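Package: repnonuniq
Title: Non-Uniqueness of Object Representations in Goal-Driven
    Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for demonstrating and quantifying the non-uniqueness of
    penultimate-layer object representations in convolutional networks
    trained only for categorization accuracy. Provides a synthetic labeled
    image generator with controllable noise, a compact CNN engine for a
    small configuration grammar (convolution, batch normalization,
    max-pooling, fully connected layers), exact constructions that produce
    representations with identical categorization behavior but no linear
    relation (softmax argmax invariance under monotone transforms and a
    Moore-Penrose pseudo-inverse preimage), two training schemes for
    similar-performing network pairs, and explained-variance analyses of
    representation equivalence under noise, stimulus-set size, and
    kurtosis-based neuron selectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    MASS
Config/testthat/edition: 3
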