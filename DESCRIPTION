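Package: gibbsColoc
Title: Object-Based Spatial Interaction Analysis from Nearest-Neighbour
    Distances
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers effective pairwise interaction potentials between two
    populations of sub-cellular objects (e.g. virus particles and endosome
    outlines) from nearest-neighbour distance distributions. The cellular
    context is corrected for via the state density q(d), the null
    distribution of distances for a uniformly placed object given the
    reference objects and the cell outline. On top of the resulting Gibbs
    distance model the package provides classical object-based
    co-localization measures with exact binomial tests and power analysis,
    Monte Carlo rank tests based on sufficient statistics of parametric
    potentials, a non-parametric chi-square-style interaction test,
    maximum-likelihood estimation of parametric and penalised
    non-parametric potentials (including pooled fits with a common length
    scale across cells), and a synthetic-scenario generator so that every
    statistical component can be exercised without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    Rcpp,
    png,
    tiff,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
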