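Package: svhbench
Title: Benchmarking Harness for Automated Sharp-van der Heijde Scoring of
    Rheumatoid Arthritis Radiographs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluation machinery for benchmarking algorithms that quantify
    radiographic joint damage in rheumatoid arthritis against expert
    Sharp-van der Heijde (SvH) scores. Provides a validated data model for
    the SvH scoring scheme (joint space narrowing and erosion over hands,
    wrists and feet, 448-point maximum) with CSV serialization, the
    patient-weighted log-RMSE evaluation metric with its 8-bin weighting
    scheme, bootstrap Bayes-factor model ranking with tie detection,
    FDR-corrected pairwise t tests, cumulative top-k mean ensembles,
    cross-dataset concordance validation, and a synthetic-data module that
    simulates zero-inflated right-skewed score cohorts, noisy team
    submissions and paired expert readers so the full pipeline is testable
    without any radiographs.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
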