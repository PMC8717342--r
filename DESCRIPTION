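Package: phenoENM
Title: Phenology-Aware Ensemble Ecological Niche Modelling
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for phenology-aware ensemble ecological
    niche modelling. Reads georeferenced occurrence records, applies a
    standard coordinate-cleaning pipeline with per-rule accounting, filters
    records in environmental space on a bin grid, generates month-matched
    pseudoabsences at a 1:1 ratio, fits an ensemble of nine classifiers
    (logistic regression, k-nearest neighbours, Gaussian process, decision
    tree, random forest, neural network, AdaBoost, naive Bayes, and
    quadratic discriminant analysis) on standardized monthly precipitation
    and minimum-temperature covariates, scores each by AUC-ROC on a
    stratified hold-out, and projects monthly habitat suitability under
    current and future climate scenarios across circulation-model variants.
    Includes a synthetic-world generator (virtual climates, virtual species
    with Gaussian niches and early or late phenology, contaminated
    occurrence sets) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mgcv,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
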