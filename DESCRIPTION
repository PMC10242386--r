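Package: panelDx
Title: Stage-Informed Biomarker Panel Discovery and PCA/K-Means Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers minimal diagnostic biomarker panels from stage-labeled
    gene expression cohorts and trains an unsupervised cancer-vs-normal
    classifier on them. Genes are filtered for minimal variation, transformed
    to log-CPM with voom precision weights, and ranked by two stage-informed
    models fit per gene with empirical-Bayes moderation: a linear model on
    stage indicator variables and an ordinal model treating stage as numeric.
    The consensus of the two rankings is minimised by Boruta shadow-feature
    selection, recursive feature elimination, and iterative variance
    inflation factor elimination. A PCA of the panel subspace (component
    count chosen by Kaiser-Guttmann, scree-elbow and cumulative-variance
    criteria) feeds a k-means classifier whose clusters are mapped to
    diagnostic classes; projection-based prediction, margin scores and
    confusion-matrix/AUROC metrics are provided, together with a synthetic
    stage-structured cohort generator with planted ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    ranger,
    caret,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    randomForest,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
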