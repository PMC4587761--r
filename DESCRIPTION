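Package: hullvote
Title: Convex-Hull Selective-Voting Ensemble Classification for Small Proteomic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-class ensemble classifier whose members are
    pairs of predictors with class-specific convex hulls trimmed to complete
    separation, voting selectively with abstention. Includes spectral-count
    preprocessing (replicate averaging, total-count normalization, sparsity
    filtering), repeated k-fold cross-validation with five performance
    indices and t-based margins of error, a label-permutation validity
    control, Fisher's exact tests on dichotomized clinical covariates,
    prominence tabulation of frequently selected predictor pairs, and a
    synthetic cohort generator with class-conditional negative-binomial
    spectral counts for end-to-end testing without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
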