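Package: heatadapt
Title: Predicting Rectal Temperature Adaptation from Heart Rate, Sweat
    Rate, and Thermal Sensation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for assessing whether heat acclimatization and heat
    acclimation lowered an athlete's end-of-exercise rectal temperature
    using only field-measurable surrogates. Implements single-split
    entropy-minimizing cut-point discovery on pre/post adaptation deltas
    of peak heart rate, whole-trial sweat rate, and peak thermal
    sensation; a count-of-criteria classifier over the three cut-point
    rules; and the full diagnostic evaluation layer (per-category
    positive predictive values, sensitivity/specificity, likelihood
    ratios, a count-threshold ROC sweep, one-way ANOVA with Fisher's LSD
    contrasts, and Hedges' g effect sizes). Because raw trial data for
    this design are rarely shareable, the package ships a seeded
    synthetic cohort generator whose phase-level summary statistics and
    predictor-outcome coupling emulate the published regime, plus a
    deterministic fixture reproducing the published contingency counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
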