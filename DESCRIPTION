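Package: PanelVote
Title: Reproducibility-Driven Discovery and Benchmarking of CSF Protein
    Biomarker Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cross-study vote-counting discovery of cerebrospinal fluid
    protein biomarker panels, with harmonized multi-cohort preprocessing
    (missingness filtering, quantile normalization, log2 and z-score
    transforms), amyloid/tau status derivation from CSF biomarker ratios,
    diagnostic evaluation by ROC/AUC with DeLong or bootstrap confidence
    intervals and Youden operating points under repeated cross-validation
    or external-validation regimes, median-split Cox proportional-hazards
    prognostic stratification with Kaplan-Meier summaries,
    covariate-adjusted per-protein clinical association with
    Benjamini-Hochberg correction, and a uniform head-to-head benchmarking
    harness over a packaged registry of published signatures. A synthetic
    multi-cohort generator with planted differential proteins, platform
    effects, missingness and right-censored progression outcomes makes
    every stage testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    survival,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
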