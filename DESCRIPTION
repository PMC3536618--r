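Package: chemoMGP
Title: Cell-Line-Derived Multi-Gene Predictors of Chemotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates multi-gene predictors (MGP) of chemotherapy
    sensitivity trained on cell-line panels. Converts plate-level cell counts
    from in vitro dose-response assays into survival fractions and an
    area-under-the-dose-response-curve (AUC) sensitivity score, filters and
    standardizes log2 microarray expression matrices, fits a supervised
    principal-components regression model (univariate feature screening with
    a cross-validated coefficient threshold, first principal component of the
    selected probes, least-squares scoring), and scores independent patient
    cohorts blinded to outcome. Validation statistics include the Wilcoxon
    rank-sum test, ROC analysis with DeLong confidence intervals, univariate
    and multivariate logistic regression odds ratios, and permutation-based
    gene-set enrichment. Includes synthetic-data generators emulating a
    cell-line panel with planted informative probes and a patient cohort whose
    binary response follows a logistic function of the same latent sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    fgsea
Config/testthat/edition: 3
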