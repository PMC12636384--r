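Package: csgsa
Title: Comprehensive Serum Glycopeptide Spectrum Analysis for
    Gastrointestinal Cancer Screening
Version: 0.1.0
Authors@R:
    person("CSGSA", "Developers", email = "csgsa@example.org",
           role = c("aut", "cre"))
Description: Tools for serum glycopeptide-based cancer screening: a
    synthetic-cohort simulator with known ground truth, LC-MS peak
    alignment and three-step enriched-glycopeptide (EGP) selection,
    in-silico glycopeptide enumeration and neutral-mass assignment,
    differential biomarker screening with volcano classification,
    tiered machine-learning models (tumor markers, signature
    glycopeptides, PCA-reduced EGP profiles) evaluated under repeated
    train/test splits with pooled ROC, and prevalence-adjusted
    screening metrics (CSGSA score, PPV/NPV on a reference
    population).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
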