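Package: fireclades
Title: Dating the Origin of Fire-Adapted Traits on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian ancestral-state reconstruction of binary fire-related
    traits on ultrametric chronograms using continuous-time Markov models and
    reversible-jump MCMC, Pagel-style correlated-evolution tests summarised by
    harmonic-mean log-Bayes factors, a two-area dispersal-extinction-
    cladogenesis (DEC) model for ancestral habitat reconstruction, corrected-
    posterior node assignment with stem propagation for dating trait origins,
    and sister-clade net speciation rate comparisons at habitat-divergence
    events. Includes seeded simulators for chronograms, traits and habitat
    ranges so the full inference chain can be exercised end to end on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    phytools,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
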