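Package: agesig
Title: Aging-Dependent Tumor Aggressiveness Signatures from Multi-Omics Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and evaluate aging-dependent tumor
    aggressiveness gene signatures from bulk expression, copy-number and
    clinical data. Provides a reproducible synthetic multi-omics cohort
    generator with planted ground truth; negative-binomial GLM
    likelihood-ratio differential expression with covariate adjustment;
    a four-step covariate-stratified signature selection pipeline with
    internal validation; eigenvalue-weighted PCA composite scoring and
    aggressiveness cluster stratification; gene-level copy-number
    gain/loss calling, frequency and expression-linkage analysis;
    gene-set over-representation, agglomerate z-scores and single-sample
    enrichment; correlation-filtered regulatory network loop detection;
    and the association, survival and prediction-performance statistics
    (chi-square, logistic/Cox models, ROC/AUC, DeLong, concordance index,
    Brier score) used to rank aggressiveness clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    survival,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
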