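Package: RectalSubtypes
Title: Discovery and Classification of Rectal Cancer Transcriptional Subtypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and classifying transcriptional subtypes of
    rectal cancer from multi-batch gene expression cohorts. Implements the full
    discovery path: merging and deduplicating expression studies, quantile
    normalisation and location-scale batch correction, Monti consensus
    clustering with deltaK model selection, Spearman co-expression networks
    with topological-overlap-based gene module detection, a gradient-boosted
    multiclass classifier on gene-module median scores, and Kaplan-Meier /
    log-rank survival analysis including tabulation of subtype shifts in
    matched pre/post-treatment sample pairs. A synthetic-cohort generator with
    planted modules, subtypes, batch effects, survival and treatment shifts
    makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    limma,
    xgboost,
    igraph,
    fgsea,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    cluster,
    mclust,
    withr,
    optparse,
    knitr
biocViews: GeneExpression, Clustering, Classification, Survival, Network
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'syntheticCohort.R'
    'preprocess.R'
    'consensus.R'
    'network.R'
    'modules.R'
    'classifier.R'
    'survival.R'
    'io.R'
    'pipeline.R'
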