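Package: emostair
Title: Adaptive Staircase Simulation and Analysis of Audiovisual Vocal
    Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-alternative forced-choice vocal emotion
    recognition experiments on a voice-morph caricature continuum and
    analyses them the way adaptive psychophysics studies of cochlear
    implant users are analysed. Provides the stimulus-design
    combinatorics of a fixed-intensity and an adaptive experiment, a
    generative observer model (logistic psychometric function with lapse
    over morph level, skewed reaction times, quality-of-life scores
    rank-correlated with auditory performance), a transformed up-down
    staircase targeting 75 percent correct via four-trial rounds,
    trial-filtering and scoring rules (audiovisual benefit and cost
    difference scores, caricature-slope scores), an iterative
    pair-removal procedure for matching groups on auditory-only
    performance, and an inferential layer (Student and Welch t tests,
    Spearman correlations, mixed repeated-measures ANOVA with
    Huynh-Feldt sphericity correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
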