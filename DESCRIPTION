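Package: vocalaccom
Title: Vocal Dialect Accommodation Analysis for Animal Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify vocal dialect accommodation in animal call
    recordings, built around translocation-style study designs in common
    marmosets. Provides per-call acoustic parameterization (fundamental
    frequency contour tracking, jitter, spectral energy quartiles,
    frequency-modulation rate and extent), principal component reduction
    with Horn parallel-analysis retention, crossed permuted discriminant
    function analysis (pDFA) controlling for caller identity, a
    variance-weighted principal-component vocal-distance metric against
    trimmed-mean population centroids, and linear mixed-effects models of
    accommodation over exposure time with likelihood-ratio tests and
    marginal/conditional R-squared. Includes a synthetic call and
    feature-table generator with known dialect structure and convergence
    dynamics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
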