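Package: alngraph
Title: Patient-Similarity Graph Neural Networks for Axillary Lymph Node
    Metastasis Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for predicting axillary lymph node
    metastasis (ALNM) in early-stage breast cancer from clinicopathologic and
    axillary-ultrasound features using population (patient-similarity) graphs.
    Provides a synthetic cohort generator with configurable marginal
    distributions and planted log-odds effects, univariate logistic screening
    with Wald odds ratios, cosine-similarity graph construction with a hard
    threshold, from-scratch dense implementations of graph convolutional
    (GCN), graph attention (GAT) and graph isomorphism (GIN) networks with
    analytic gradients and an Adam optimizer, and a full clinical evaluation
    battery (confusion-matrix metrics, ROC/AUC with bootstrap confidence
    intervals, precision-recall curves, and inter-model agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
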