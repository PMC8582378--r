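Package: msitma
Title: Supervised Classification of MALDI Mass Spectrometry Imaging Tissue Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for binary classification of tissue-microarray
    MALDI mass spectrometry imaging data: reading and writing continuous-mode
    imzML, total-ion-count normalization, harmonized m/z binning with
    square-root dynamic-range reduction, two fully specified neural
    classifiers (a multilayer perceptron and a 12-layer one-dimensional
    convolutional network) fused by confidence averaging, median-based
    per-tissue-group classification, and leave-one-TMA-out or balanced k-fold
    cross-validation with per-fold metric reports. Includes a seeded synthetic
    cohort generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
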