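Package: autoprt
Title: Automated Positive-Reinforcement Training for Group-Housed Macaques
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A software re-implementation of an automated positive-reinforcement
    training (PRT) system for group-housed rhesus macaques: a deterministic,
    seeded engine for the cued button-press task (hold-time scoring, error
    time-outs with prolongation, cue persistence after errors, 1/2/4-button
    variants), the training-progression protocol (per-session success
    criterion, laboratory session-duration ramp), a generative model of
    simulated subjects with User/Non-User/Unexposed learner archetypes, a
    plain-text session-log format with readers, writers and validators, and
    the behavioural-analysis pipeline (correct presses per hour, percent
    correct, breeding-facility classification, sessions-to-criterion,
    analysis windows, group summaries, exact Mann-Whitney and Kruskal-Wallis
    rank tests, and linear regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
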