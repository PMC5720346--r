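Package: coupledDE
Title: Cross-Study Replication of Differential Expression with Coupled
    Signature Scoring
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying replicated case-control differential
    expression across two independent transcriptome studies and for scoring
    subjects on a coupled two-signature axis. Implements covariate-adjusted
    per-gene linear models with empirical-Bayes moderated t-statistics
    (asymptotic and stratified-permutation p-values), selection of a p-value
    threshold at which the cross-study overlap of significant genes is at
    least twice its chance expectation, sign-concordant consensus gene sets,
    Fisher's combined probability test with Benjamini-Hochberg FDR control,
    per-term Fisher's exact gene-set enrichment with Bonferroni correction,
    and a per-subject projection score ("bioscalar") along the regression
    line coupling mean UP and mean DOWN signature expression, with Cohen's d,
    ROC AUC and tertile-based subgroup classification. A synthetic-data
    module generates paired case-control studies with planted ground truth
    so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    jsonlite,
    withr
biocViews: GeneExpression, DifferentialExpression, Microarray,
    StatisticalMethod, Transcriptomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
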