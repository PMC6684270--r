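Package: vocomotor
Title: Developmental Analysis of Vocal, Locomotor and Arousal Coordination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for studying how infant vocal
    behavior, locomotor activity and autonomic arousal co-develop over the
    first weeks of life. Provides per-call acoustic scoring (duration,
    Wiener entropy), video frame-difference locomotor activity indices,
    ECG beat detection with inter-beat-interval validation and within-session
    heart-rate percentiles, maturity-index developmental trajectories with
    transition-day estimation, peri-event spline dynamics with bootstrap
    confidence bands and an event-timing-scramble null, a linear
    mixed-model suite with Bonferroni-Holm correction, and a synthetic-study
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    Matrix,
    signal,
    lme4,
    lmerTest,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
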