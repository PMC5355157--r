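Package: progsig
Title: Prognostic Gene Signature Discovery from Expression and Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering and validating weighted prognostic
    gene signatures from transcriptomic case-control studies and survival
    cohorts. Provides cross-study differential-expression consensus,
    per-gene median-split survival screening with family-wise error control,
    signed Spearman co-expression networks with community detection and
    negative-bridge gene identification, resampling stability selection of a
    Cox proportional-hazards signature with averaged coefficients, and
    score-based validation (test-set forest statistics, external-cohort
    scoring, multivariate adjustment, subtype stratification). Includes a
    self-contained survival kernel (Kaplan-Meier, log-rank, Efron-corrected
    Cox fitting, forward-conditional stepwise selection) and seeded
    synthetic-data generators with planted ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    fgsea
Suggests:
    survival,
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
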