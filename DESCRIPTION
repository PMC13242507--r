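Package: emoblend
Title: Scoring and Inference for Blended-Emotion Perception Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-scale judgment data from blended-emotion
    recognition experiments, in which raters judge stimuli expressing pairwise
    combinations of anger, disgust, fear, happiness and sadness at varying
    prominence proportions on 0-10 intensity scales. Implements three accuracy
    indices (generous, strict, very strict), exact combinatorial chance levels
    for fixed and variable numbers of selected scales with a Monte-Carlo
    random-responder oracle, one-way repeated-measures ANOVA with Mauchly's
    test, Greenhouse-Geisser correction and partial/generalized eta squared,
    Bonferroni-corrected post-hoc contrast families, a generative rater
    simulator with confusion kernels for calibration and recovery studies, and
    an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
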