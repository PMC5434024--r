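Package: rmabgame
Title: Social-Learning Equilibria in a Restless Multi-Armed Bandit Game
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the steady-state analysis of a population of agents
    facing a restless multi-armed bandit with a single good arm. Uninformed
    agents either search for the good arm themselves (individual learning,
    success probability q_I) or copy a currently informed agent (social
    learning, success probability q_O), and the good arm relocates at rate
    q_C/N per turn. The package provides the closed-form steady-state fitness
    of every agent, the exact 2^N Markov chain over knowledge states
    (transition matrix, stationary distribution, spectral gap and relaxation
    time), solvers for the unique mixed-strategy Nash equilibrium (an
    evolutionarily stable strategy in the sense of Thomas) and the
    Pareto-optimal strategy, numerical certificates for the equilibrium's
    stability and for the fitness ordering that resolves Rogers' paradox, a
    seeded turn-by-turn Monte Carlo simulator with batch-means error
    estimates, and a small command-line interface for tables and parameter
    sweeps.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
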