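Package: devfeedbacks
Title: Behaviour-State Feedbacks in Incremental Behavioural Development
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the adaptive incremental development of a behavioural
    phenotype under environmental uncertainty. Individuals facing one of two
    environments receive imperfect cues, integrate them by Bayes' rule, and at
    each of T timesteps commit an irreversible unit increment toward one of two
    phenotypic specializations; terminal fitness depends on the number of
    increments matching the true environment through a concave, convex or
    linear fitness landscape. The package computes exact optimal policies by
    finite-horizon stochastic dynamic programming, simulates populations
    following those policies, and derives the analyses that expose
    behaviour-state feedback loops: decision-threshold curves, phenotypic
    phase diagrams, phenotype-distribution summaries (including Sarle's
    bimodality coefficient) and cue-reliability sweeps. Brute-force expectimax
    and exhaustive policy-search oracles are included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
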