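Package: raschlink
Title: Concurrent Rasch Calibration of Multiple Instruments via Equate Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links related measurement instruments onto one common logit scale
    by fitting a dichotomous Rasch model in which groups of similar items
    ("equate clusters") are constrained to share a single difficulty. Provides
    pairwise conditional estimation for incomplete multi-instrument designs,
    infit/outfit and dedicated equate-cluster fit statistics, an ANOVA-based
    differential item functioning test on standardized residuals, fit-based
    item purification, weighted-likelihood person scoring against a frozen
    item key, and a Monte-Carlo simulation framework that evaluates scale
    alignment (correlation with true difficulties and between-instrument
    misalignment) under varying item overlap, anchor placement, ability
    differences, and anchor misspecification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
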