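Package: spikeplan
Title: Goal-Directed Planning with Networks of Stochastic Spiking Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles Markov decision processes (and basis-function
    approximations of continuous control tasks) into recurrent networks of
    stochastic spike-response neurons whose steady-state population activity
    encodes the Bellman-optimal state values. Provides exact dynamic
    programming oracles (value iteration, policy evaluation, open-loop
    enumeration), generators for a zoo of benchmark tasks (two-step door
    maze, blackjack, flag maze, pendulum swing-up, binary economic choice,
    sequential movement chains, a devaluation maze), a mean-field rate
    simulator and a stochastic spiking simulator, value/policy decoding from
    population activity, local delta-rule plasticity that learns the network
    weights from sampled transitions, a spike-count-difference decision
    readout with psychometric and chronometric analyses, and a
    spreading-activation baseline planner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
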