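Package: inflammclock
Title: Inflammatory Aging Clock for Glioblastoma Transcriptomic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates a transcriptomic inflammatory aging clock
    (iAge) for glioblastoma cohorts. Inflammation-related genes whose
    expression tracks chronological age are selected by Spearman screening,
    combined into a calibrated per-patient inflammatory age, and used to
    split cohorts into high- and low-iAge subtypes. Prognostic value is
    quantified with first-principles survival machinery (Kaplan-Meier with
    Greenwood variance, two-group log-rank, univariate Cox regression with
    Breslow tie handling) together with conditional annual survival tables,
    gene-set randomization tests, stemness-index correlations and a paired
    Wilcoxon differential-expression screen. A synthetic cohort generator
    with known ground truth (age-linked genes, latent inflammatory hazard,
    independent censoring, stemness correlations, exclusion flags) makes
    every stage testable without access to the original tumor databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
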