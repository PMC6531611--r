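Package: actisleep
Title: Daily Bidirectional Sleep and Physical Activity Analysis from
    Dual-Device Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for micro-longitudinal analysis of the day-to-day
    coupling between nighttime sleep and daytime physical activity from
    dual-device actigraphy (a wrist accelerometer recording 30-second
    epoch counts, off-wrist status and white light, plus a hip
    accelerometer recording 1-second vertical-axis counts). Provides a
    synthetic cohort generator with known ground truth, rule-based sleep
    interval scoring (count-threshold onset/offset, interval splitting,
    main-sleep selection, maintenance efficiency, validity rules),
    hip-count minute classification behind a pluggable classifier
    (non-wear detection, 60-second window features, a trainable reference
    network), sleep-onset-anchored person-day construction with daily
    MVPA/sedentary totals and MVPA-cluster timing, and two-level linear
    mixed models with a random intercept and AR(1) within-person errors,
    estimated by profiled maximum likelihood with within-/between-person
    decomposition of daily predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
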