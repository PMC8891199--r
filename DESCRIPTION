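Package: cogflex
Title: Simulation and Q-Learning Analysis of Rodent Cognitive-Flexibility Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Engines for two operant tasks used to assay executive function in
    rodents: a two-lever probabilistic reversal learning (PRL) task with
    stochastic 80/20 reward contingencies that reverse every 40 trials, and the
    5-choice serial reaction time task (5CSRTT) with its standard impulsivity
    and attention manipulations. Provides a four-parameter Rescorla-Wagner
    Q-learning model of PRL choice (dual learning rates, stickiness, inverse
    temperature) fit per session by multi-start bounded maximum likelihood,
    a parameter-recovery harness, the standard PRL behavioural statistics
    (per-block high-lever presses, win-stay/lose-shift, sliding-window choice
    fraction, pellets earned), the six per-session 5CSRTT measures, and a
    synthetic cohort generator emulating a 2x2 group-by-sex study design so
    the whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lhs,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
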