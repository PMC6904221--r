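Package: phenostrat
Title: Deep Phenotype Stratification of Diabetes Cohorts from Electronic
    Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for stratifying diabetes cohorts from electronic health
    record (EHR) data layers: dictionary-based tagging of clinical notes
    with fuzzy matching and negation suppression, BM25 weighting of
    combined assigned and text-mined diagnosis codes, Markov clustering
    (MCL) of thresholded patient cosine-similarity networks with
    perturbation-based stability analysis scored by Variation of
    Information, symptom-block grouping of clusters, stratum-corrected
    enrichment and comorbidity-pair statistics with temporal
    directionality, and a five-criterion glycemic dysregulation score
    derived from HbA1c time series (Bayesian online change-point
    detection, mixed-effects onset estimates, severity bins). A
    synthetic-cohort generator with planted cluster, mention, change-point
    and dysregulation structure supports end-to-end validation without
    access to confidential patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    lme4,
    Matrix,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ape,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
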