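Package: ordlmi
Title: Longitudinal Measurement Invariance and Latent Distribution
    Diagnostics for Ordinal Symptom Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying treatment response in repeatedly
    administered ordinal symptom questionnaires (GAD-7- and BDI-style
    inventories).  Implements the longitudinal ordinal factor-analysis
    sequence for measurement invariance testing (configural, loadings,
    threshold, and unique-factor levels) with diagonally weighted least
    squares estimation on polychoric correlations and thresholds;
    chi-square difference and RMSEA-based equivalence testing with the
    usual fit indices (RMSEA, CFI, SRMR); pairwise latent-normality
    tests from two-way contingency tables; semi-nonparametric latent
    density estimation for graded items via Davidian curves with
    Hannan-Quinn order selection; zero-inflation score tests for
    endorsed-symptom counts; latent versus sum-score treatment-effect
    comparisons including tail risk ratios; and a synthetic-cohort
    generator producing liability-threshold ordinal data with monotone
    dropout for testing every stage without access to register data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
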