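Package: biplink
Title: Link Prediction in Static and Temporal Bipartite Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Similarity indices for predicting missing links in bipartite
    networks and future links in temporal bipartite networks, aimed at
    biomedical applications such as drug-target interaction screening and
    disease forecasting in multimorbidity patient cohorts. Implements the
    classical bipartite local indices (common neighbours, Jaccard,
    Adamic-Adar, resource allocation, preferential attachment), the
    local-community-paradigm (CAR/LCL) family, a path-based resource
    allocation index built on unique paths of length three, and a temporal
    probabilistic extension that weights each path by the estimated
    conditional probability of one disease following another. Includes
    train/probe evaluation with the pairwise-comparison AUC estimator,
    rank-based AUROC, precision/recall/F-score, repeated-run benchmarking,
    degree-bias diagnostics, a synthetic temporal multimorbidity cohort
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
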