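Package: explorehorizon
Title: Exploration Strategies in a Three-Option Horizon Bandit Task
Version: 0.1.0
Authors@R: person("Jo", "Hartley", email = "jo.hartley@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how people balance exploration and
    exploitation in a child-friendly three-option restless-free bandit task
    with short (one draw) and long (six draw) decision horizons.  The package
    generates balanced task schedules, simulates agents from a twelve-member
    family of choice models (Thompson sampling, upper-confidence-bound, and a
    hybrid core, each optionally extended with epsilon-greedy value-free
    random exploration and/or a novelty bonus), fits model parameters to
    first-draw choices by multi-start maximum likelihood, compares models by
    K-fold cross-validated held-out likelihood and random-effects Bayesian
    model selection, runs parameter- and model-recovery simulations, computes
    behavioural signature metrics (low-value and novel bandit choice
    frequencies, familiarity, expected value, reward trajectories), and
    performs the associated group statistics (mixed-design ANOVA, partial
    correlations, clinical cutoff splits) on synthetic cohorts that emulate a
    developmental study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
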