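Package: bmirl
Title: Actor-Critic Reinforcement Learning Decoders for Closed-Loop
    Brain-Machine Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for brain-machine interface
    (BMI) decoders that adapt from an evaluative feedback signal instead of
    a supervised error. Provides direction-tuned synthetic primary motor
    cortex (M1) ensembles built on the Izhikevich spiking-neuron model,
    synthetic nucleus accumbens (NAcc) units with goal-approach
    reward-expectation modulation, a gamma-memory time-delay neural-network
    Actor with per-action value outputs trained by a scalar
    temporal-difference-like feedback, a tap-delay multilayer-perceptron
    Critic that classifies rewarding versus aversive neural states, 2D grid
    and 3D reaching task environments, closed-loop experiment protocols
    (sequential novel targets, tuning-map reorganization, surrogate random
    feedback), and perievent time-histogram analysis with
    Kolmogorov-Smirnov response categorization of accumbal units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
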