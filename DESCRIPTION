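Package: pitchmimic
Title: Simulation and Scoring of Sung and Whistled Pitch Imitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pitch imitation across motor systems: random
    composition of short melodies under interval and octave constraints,
    synthesis of whistle-timbre sine stimuli with WAV output, a generative
    simulator of imitation performances built on a propagation-of-error model
    (shared perceptual noise, modality-specific motor noise, constant bias and
    linear compression of errors toward each performer's habitual pitch),
    cents-based accuracy and precision scoring with the standard exclusion
    filters, and the corresponding inferential stage: nested random-intercept
    linear mixed models with Kenward-Roger tests, 2-SD standardized estimates,
    cluster bootstrap confidence intervals and partial correlations.
    Includes an end-to-end parameter-recovery harness for the generative model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    data.table,
    lme4,
    pbkrtest,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    lmerTest
Config/testthat/edition: 3
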