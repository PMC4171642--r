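Package: stromasig
Title: Stromal Gene-Signature Discovery and Prognostic Evaluation for
    Carcinoma-Associated Fibroblasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discover and evaluate prognostic gene-expression
    signatures of carcinoma-associated fibroblast (CAF) state in bulk tumour
    transcriptomes. Implements paired CAF/NCF differential-expression
    filtering, resampling-based stability selection with L1-penalized
    logistic regression, an equal-weight signed z-score risk statistic with
    a tertile cutoff, per-dataset standardization for meta-cohort pooling,
    Kaplan-Meier / Cox / ROC evaluation, likelihood ratios with Bayesian
    post-test recurrence probabilities, a collagen-based stromal-content
    proxy, and qPCR reference-gene normalization (geNorm and delta-Ct).
    A synthetic cohort generator with planted CAF-state genes, a latent
    stromal fraction and censored survival outcomes makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pROC,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
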