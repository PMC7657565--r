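Package: rewardsurprise
Title: Simulation and Dissociation of Reward Prediction Error, Rare-Reward,
    and Visuospatial Surprise Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing reward-schedule experiments in
    which scalar reward prediction errors, rare-reward events, and visuospatial
    surprise are decorrelated by construction. Provides count-enforced reward
    schedule generators for stable, changing, and equiprobable session types; a
    generative behavioural agent producing lapses and gamma-distributed
    reaction times; Rescorla-Wagner learning-rate estimation from
    lagged-reward regression weights; hierarchical logistic lapse and gamma
    reaction-time models with likelihood-ratio tests; gamma-HRF event-related
    fMRI design construction with shared-variance diagnostics; synthetic ROI
    BOLD simulation with AR(1) noise; session-level GLMs with two-level group
    combination; and peristimulus time-course extraction. All results are
    returned as tibbles with broom-style tidiers and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
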