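Package: choiceadapt
Title: Memory and Learning Models of Choice Adaptation in Dynamic Risky
    Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses repeated binary choice between a safe
    (or static risky) option and a dynamic risky option whose high-outcome
    probability changes linearly across trials. Implements an Instance-Based
    Learning model (ACT-R style activation with power-law memory decay and
    logistic retrieval noise, blended values, deterministic choice) and two
    reinforcement-learning models (delta and decay expectancy updating with
    softmax choice), individual-level maximum-likelihood fitting (grid search
    with Monte-Carlo-averaged predictions for the instance model; multi-start
    Nelder-Mead for the reinforcement-learning models), and the adaptation
    analyses built on them: maximization rates by task period, adaptive and
    recency median splits, and calibration-to-test generalization
    simulations. Includes a synthetic-cohort generator with known ground
    truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    ggplot2,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
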