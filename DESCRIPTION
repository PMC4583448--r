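Package: selvote
Title: Selective Voting Ensemble Classification for Two-Group Biomarker Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a selective voting ensemble classification approach
    (SVA) for discriminating two clinical groups from a small panel of
    biomarkers. Every unordered pair of markers trains its own two-class
    base classifier (LDA, QDA, Gaussian naive Bayes, or linear SVM) and
    votes on each held-out sample across many randomized leave-k-out
    cross-validation realizations. Vote fractions yield per-sample
    proclivity scores, marker pairs that vote consistently form persistent
    ensemble sets, and overlaps between those sets produce a between-sample
    consensus map that exposes within-group heterogeneity. Includes a
    moment-matched log-normal synthetic cohort generator for salivary
    biomarker panels, performance scoring against clinical labels, mismatch
    sample identification, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    MASS,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
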