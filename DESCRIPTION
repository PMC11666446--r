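Package: ebmscale
Title: Body Size-Independent Scaling of Peak Oxygen Uptake with Exercise
    Body Mass
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Scaling of peak oxygen uptake (VO2peak) from treadmill
    cardiopulmonary exercise testing with the exercise body mass (EBM)
    metric, an allometric combination of body mass, height, sex, and age.
    Implements the generalized prediction equation VO2peak = 11 x EBM x WL,
    where the workload (WL) term combines treadmill speed, fractional
    grade, and heart-rate reserve; log-linear backward-elimination
    refitting of the scaling exponents; a reproducible synthetic
    cardiopulmonary-exercise cohort generator; and an evaluation suite
    covering body-size independence by workload bin, calibration slopes
    across sex, age, and BMI subgroups, effect-size contrasts, and
    heart-failure slope analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
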