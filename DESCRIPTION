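Package: stochswitch
Title: Stochastic Switch Model of C. elegans Random Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing Caenorhabditis elegans random-search
    locomotion as a four-state hidden Markov process driven by a stochastic
    flip-flop circuit of forward and reverse command-neuron pools. Provides
    track kinematics and signed tangential-velocity construction, per-state
    velocity emission densities with a Cauchy pause core, continuous-time
    Markov chain machinery with a synaptic-weight parameterization,
    maximum-likelihood rate fitting by constrained random optimization with
    Viterbi and Forward-Backward decoding, run-length and search-mode
    analytics, escape-motif limits, and a point-worm simulator for synthetic
    cohorts and chemotaxis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
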