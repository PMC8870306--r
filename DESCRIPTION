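Package: gsnpi
Title: Multi-Omics Gene Similarity Network Maps for Nottingham Prognostic
    Index Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies breast-cancer samples into Nottingham Prognostic
    Index (NPI) levels from three omics layers (gene expression, copy number
    alteration, mRNA). Implements a hybrid feature selector (summed-expression
    chi-square ranker plus mutual-information mRMR with a random-forest
    forward search), embeds selected genes into 2-D gene similarity network
    (GSN) templates via t-SNE or a self-organizing map, renders per-sample
    colored maps (merged RGB or per-omic concatenated), balances classes with
    elastic-deformation augmentation, and trains compact VGG- and
    ResNet-style convolutional classifiers with softmax/cross-entropy.
    Includes NPI scoring and level binning, Kaplan-Meier relapse-free
    survival curves per level, a clinically consistent synthetic-cohort
    generator, and an end-to-end pipeline with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    pROC,
    png,
    ranger,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
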