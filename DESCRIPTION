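Package: prlt
Title: Simulation, Model Fitting and Group Analysis for the Prosocial
    Reinforcement Learning Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-armed probabilistic reversal bandit tasks in which
    reward recipients alternate between the participant ("self") and another
    person ("other"). Builds deterministic reversal schedules, simulates
    Rescorla-Wagner delta-rule learners with softmax choice, fits null, shared-
    and separate-parameter models per subject and block by maximum likelihood,
    compares them with summed BIC, runs posterior predictive checks and
    learning-rate/inverse-temperature grid simulations, generates synthetic
    cohorts with planted observation effects, and carries out the group-level
    statistics: prosocial learning sensitivity (PLS) scoring and
    selfish/prosocial categorization, mixed repeated-measures ANOVA,
    FDR-corrected paired post-hocs, and bootstrap robustness checks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
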