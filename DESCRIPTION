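Package: phytoscreen
Title: Ensemble QSAR Screening of Natural Compounds Against Cancer Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ensemble-based multi-objective virtual-screening pipeline for
    phenotypic (cell-line) bioactivity data. Covers curation of compound to
    cell-line IC50 records (standardization, activity labeling, replicate
    consistency), 1,024-bit circular fingerprints, cluster-based
    undersampling, a PCA-Euclidean applicability domain, genetic-algorithm
    variable selection for random-forest, decision-tree and k-nearest-neighbor
    classifiers under a balanced-classification-rate fitness, genetic-algorithm
    ensemble optimization with mean-probability aggregation, early-recognition
    scoring (RIE, BEDROC, enrichment factors) of cross-cell-line consensus
    models, and prioritization of plant species by their content of predicted
    active compounds. A synthetic-data module generates every input the
    pipeline consumes so all stages are testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    class,
    cluster,
    data.table,
    jsonlite,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (the obabel executable must be on the PATH)
Config/testthat/edition: 3
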