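Package: hyperfc
Title: High-Order Functional Connectivity via Hypergraphs and Algebraic Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a shared hypergraph representation of high-order functional
    connectivity from parcellated regional time series. A group-level hyperedge
    backbone is inferred with non-negative LASSO regression (fifth-percentile
    thresholding, minimum-cardinality filtering and majority voting across
    subjects), and each hyperedge is weighted per subject by the algebraic
    connectivity (Fiedler value) of its induced absolute-correlation subgraph,
    alongside Gaussian-kernel, mean-correlation, LASSO-L2-norm and
    functional-network baselines. Downstream tools cover nonparametric group
    statistics with false-discovery-rate control and Cliff's delta effect
    sizes, random-forest classification of subject groups from hyperedge
    weights, and bootstrap mediation analysis linking a pathological exposure
    to cognitive outcomes through hyperedge weights. A latent-factor simulator
    generates synthetic cohorts with planted hyperedge structure, group
    effects, and mediation triples.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    stats,
    utils,
    graphics,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
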