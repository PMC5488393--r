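Package: metpanel
Title: Diagnostic Evaluation of Plasma Metanephrines and Methoxytyramine for
    Pheochromocytoma and Paraganglioma Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating the plasma triplet panel of normetanephrine,
    metanephrine and methoxytyramine as a screening test for pheochromocytoma,
    paraganglioma (PPGL) and head-and-neck paraganglioma (HNPGL). Implements
    age-specific upper cutoffs for normetanephrine (cubic-in-age with a cap),
    fixed cutoffs for metanephrine and methoxytyramine, pg/mL to nmol/L unit
    conversion, per-metabolite positivity flags and mutually exclusive
    combination categories, fold-elevation scores, cohort-level sensitivity
    and specificity with paired rule comparisons, rank-based ROC/AUC and
    paired AUC tests, positive likelihood ratios and prevalence-to-posttest
    probability curves, reference-population summary statistics with
    covariate-adjusted group differences, and a seeded synthetic cohort
    generator calibrated to published reference and tumor population
    characteristics so the full pipeline can be exercised without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
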