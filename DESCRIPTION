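Package: ccweight
Title: Longitudinal Body-Weight Analysis for Collaborative Cross F1 Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing longitudinal body-weight records from
    Collaborative Cross (CC) F1 mouse panels carrying a heterozygous
    gene knockout. Provides a SummarizedExperiment-based cohort container
    with CSV readers and writers, percent body-weight-gain traits, per-line
    group trajectories with Welch tests, broad-sense heritability from
    one-way ANOVA variance components, a per-line genotype-classification
    benchmark scored by repeated stratified cross-validated ROC-AUC, a
    chained linear-regression body-weight forecaster evaluated by pooled
    out-of-fold R-squared, Pearson correlation matrices across timepoints
    with heatmap export, and a synthetic cohort generator that emulates the
    study design so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    rpart,
    randomForest,
    e1071,
    class,
    pheatmap,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
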