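Package: k2tax
Title: Ensemble Recursive K=2 Partitioning for Taxonomy Discovery in
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds robust taxonomy-like binary hierarchies over samples or
    over pre-labeled sample groups (such as single-cell clusters) from a
    features-by-observations expression matrix. Each recursive K=2 partition
    is estimated from an ensemble of feature-bootstrap perturbations with
    per-perturbation variability-based feature selection, aggregated through
    a cosine (Hamann) similarity matrix whose eigendecomposition yields a
    closed-form partition-stability score. Includes constrained k-means
    (must-link groups) for group-level input, a subgroup annotation suite
    (moderated-t differential expression, hypergeometric gene-set
    over-representation, rank-based single-sample gene-set projection,
    phenotype association tests with FDR control), a hierarchical-data
    simulator, Baker's gamma and entropy evaluation metrics, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Matrix,
    data.table,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma,
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
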