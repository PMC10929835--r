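Package: cupscore
Title: Cuproptosis Regulation Patterns and the CupScore Signature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering cuproptosis regulation patterns in bulk
    tumour expression cohorts and quantifying them per sample. Implements
    resampling-based consensus clustering on a 13-gene cuproptosis regulator
    panel with PAC-based model selection, single-sample gene-set enrichment
    (ssGSEA) with unity normalisation for tumour-microenvironment scoring,
    empirical-Bayes moderated differential expression between patterns,
    univariate and multivariate proportional-hazards survival analysis,
    maximally selected survival cutpoints, time-dependent ROC, a PCA-based
    per-sample CupScore with optional LASSO-Cox gene sparsification, and
    numeric mutation/copy-number landscape summaries. Ships a seeded
    synthetic multi-omic cohort generator with planted ground truth so the
    whole pipeline can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    sva,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
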