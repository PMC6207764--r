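Package: coopcost
Title: Cost-Efficient External Incentives for Cooperation in Finite Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how an external decision-maker can promote
    cooperation in a finite, well-mixed population playing the one-shot
    Prisoner's Dilemma under pairwise-comparison (Fermi) imitation dynamics.
    Implements state-conditioned interference schemes that reward cooperators,
    exact fixation probabilities and the small-mutation-limit stationary
    cooperation frequency, absorbing-Markov-chain accounting of the expected
    total cost of interference via the fundamental matrix, closed-form
    sufficient conditions for reaching a target cooperation level, search for
    the cost-optimal investment threshold, and an agent-based Monte-Carlo
    simulator used as an independent check of the analytic results.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
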