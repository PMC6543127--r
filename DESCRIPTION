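Package: gutflow
Title: Case-Control Gut Metagenome and Metabolome Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for two-group (case/control) shotgun
    metagenome and LC-MS metabolome studies of the human gut. Provides
    abundance-profile input/output and filtering, alpha-diversity and
    rarefaction statistics, enterotype detection by Jensen-Shannon
    distance with partitioning around medoids and Calinski-Harabasz
    model selection, Wilcoxon/Benjamini-Hochberg differential abundance,
    co-abundance gene group (CAG) construction with tracer-gene taxonomy
    and odds-ratio enrichment, a cross-validated random-forest
    discrimination stage with ROC/AUC, NIPALS PLS-DA/OPLS-DA with VIP
    scores for peak-area metabolomics, microbe-metabolite Spearman
    correlation grids, and a synthetic-data generator with planted
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    randomForest,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    mixOmics,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
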