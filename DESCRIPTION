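Package: pvpatchseq
Title: Multimodal Analysis of Patch-Seq Data from Parvalbumin Interneurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Patch-seq studies of hippocampal
    parvalbumin interneurons. Provides median-absolute-deviation quality
    control, expression gating and differential-expression labeling, six
    gene-selection methods, a class-balanced random-forest classification
    protocol, linear-SVM recursive feature elimination, correlation
    k-nearest-neighbor mapping onto reference embeddings, cell-adhesion-
    molecule similarity matrices, a Gini-impurity sliding-window detector
    of age-dependent binary expression transitions with a Monte Carlo
    permutation null, and a ten-parameter intrinsic electrophysiology
    feature extractor. Includes synthetic-data generators with planted
    ground truth so every stage is testable without external data.
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
    Matrix,
    minpack.lm,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
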