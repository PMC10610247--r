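Package: faersror
Title: Disproportionality Signal Detection and Profile Clustering for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for FAERS-style spontaneous adverse-event
    report data: reading the quarterly "$"-delimited tables, case
    deduplication, chronological drug-event linkage, indication-overlap
    exclusion, MedDRA preferred-term labelling of pruritus, bivariate
    demographic association tests, reporting-odds-ratio (ROR) signal
    detection with the Haldane-Anscombe correction and Fisher's exact
    test, and multivariate profiling of drugs by covariance-matrix
    principal component analysis and Ward hierarchical clustering of
    drug-by-term lnROR matrices. A synthetic report generator with
    planted odds multipliers and a closed-form ROR oracle makes every
    stage verifiable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
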