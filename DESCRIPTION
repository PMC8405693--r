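Package: lfqStability
Title: Stability-Selected Differential Abundance for Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential-abundance analysis of label-free quantitative (LFQ)
    proteomic intensity tables with missing-not-at-random values. Implements
    median normalization, routing of sparsely quantified proteins to a
    detection-limit heuristic, repeated group-wise Gaussian imputation with
    empirical-Bayes moderated regression (disease and preparation-batch
    predictors) and stability selection across imputation rounds, q-value
    multiple-testing control, mean-t-statistic gene-set enrichment with a
    permutation null and overlap-based redundancy clustering, and
    proteome/transcriptome concordance. Includes a synthetic-data generator
    with left-censored missingness and known ground truth for calibration
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, DifferentialExpression, MassSpectrometry,
    GeneSetEnrichment, Software
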