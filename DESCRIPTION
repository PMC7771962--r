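Package: tdaxon
Title: Temporal-Difference Error Models and Fiber-Photometry Analysis of
    Striatal Dopamine Axons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dopamine-axon calcium signals recorded in
    the striatum during an odor-guided choice task with asymmetric reward
    sizes. Implements a temporal-difference (TD) error model of the task
    with perceptual noise and several action-selection policies
    (deterministic, softmax, matching, epsilon-greedy), exact and
    Monte-Carlo state-value solvers, and per-trial TD-error traces; a
    raised-cosine event-kernel encoding model fitted with cross-validated
    lasso regression; two-channel photometry preprocessing (60 Hz bandstop,
    moving-median detrending, motion-artifact regression) and event-window
    responses; reward response-function fits with zero-crossing estimation
    and anatomical regression; a mechanistic excitation/inhibition
    input-ratio circuit model; psychometric fitting and choice-bias
    analyses; a bootstrap model comparison; and a synthetic-data generator
    emulating the task's sessions and photometry so every stage is testable
    without recordings.
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
    glmnet,
    Matrix,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
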