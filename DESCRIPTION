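Package: twosteptask
Title: Simulation and Analysis of the Two-Step Sequential Decision Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generative simulator and trial-level analysis pipeline for the
    two-step sequential decision task used to dissociate model-based from
    model-free reinforcement learning. Provides the task environment
    (probabilistic transitions, Gaussian random-walk reward probabilities),
    hybrid SARSA(lambda) learning agents with valence-dependent model-based
    weights and a generative response-time layer, synthetic clinical cohorts
    (problem gamblers versus controls), engagement-based subject exclusion,
    hierarchical logistic stay-probability regressions, mixed-design
    response-time ANOVAs with effect sizes, and a severity correlation
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
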