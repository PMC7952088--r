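Package: polfret
Title: Single-Molecule FRET Trace Simulation, Idealization and Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for single-molecule FRET (smFRET) time traces of
    DNA polymerase I switching its substrate between polymerase,
    5' nuclease and exonuclease domains. Simulates donor/acceptor
    intensity traces from a continuous-time Markov kinetic scheme with
    realistic photophysics (background, leakage, Gaussian noise,
    single-step photobleaching); corrects and quality-filters traces;
    idealizes FRET trajectories with a global Gaussian-emission hidden
    Markov model fitted by Baum-Welch and decoded by Viterbi; compiles
    composite kernel-density FRET histograms, state populations and
    transition density plots; decomposes dwell-time decay rates into
    microscopic rate constants with bootstrap uncertainties; and
    estimates binding affinity from the fraction of bound frames.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    minpack.lm,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
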