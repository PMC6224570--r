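Package: polhop
Title: Polaritonic Surface-Hopping Photochemistry in Optical Cavities
Version: 0.1.0
Authors@R: person("polhop", "maintainers", email = "polhop@example.org",
    role = c("aut", "cre"))
Description: Simulates photochemistry of a two-state molecular model strongly
    coupled to a single quantized cavity mode. Builds polaritonic states from an
    extended Jaynes-Cummings Hamiltonian (two electronic states times photon
    occupations 0/1, counter-rotating terms included), propagates fewest-switches
    surface-hopping trajectories on the polaritonic surfaces with local
    diabatization and an energy-based decoherence correction, samples thermal
    initial conditions with a stochastic velocity-rescaling thermostat, and
    post-processes trajectory swarms with a stochastic cavity photon-loss model.
    Ships an analytic two-dimensional azobenzene-like photoswitch surrogate, a
    one-dimensional avoided-crossing model, and an exact split-operator grid
    oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
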