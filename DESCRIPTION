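Package: assessgame
Title: Scoring and Psychometric Evaluation of an Accelerometer-Based
    Selective Motor Control Game Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline scoring and psychometric-evaluation toolkit for a
    game-like assessment of lower-limb selective voluntary motor control
    (SVMC) measured with paired 3-axis accelerometers over the hip, knee,
    and ankle joints. Converts proximal/distal sensor traces to joint
    angles and angular speeds, imputes occasional sensor dropouts,
    computes tracking-accuracy and involuntary-movement scores
    standardized to a neurologically intact adult reference cohort, and
    provides the full validity and reliability battery: robust
    bootstrapped ANCOVA at fixed age design points, tie-corrected rank
    correlations with clinical comparators (SCALE, GMFCS, therapist
    rating), ICC(2,1) with BCa bootstrap confidence intervals, standard
    error of measurement, minimal detectable change, and correlation
    power analysis. Includes a synthetic-cohort simulator with known
    latent impairment parameters for validating the analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
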