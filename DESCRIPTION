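Package: mapent
Title: Mapping Entropy Landscapes of Coarse-Grained Protein Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to explore the space of reduced (coarse-grained, CG)
    representations of a protein. A protein structure is encoded as an
    attributed contact graph (heavy-atom vertices with physicochemical
    binary features, inverse-distance edge weights under a 1 nm cutoff),
    and a candidate CG mapping -- a fixed-size subset of retained atoms --
    is written into the vertices as a binary site flag. The information
    lost by a mapping is quantified by the mapping entropy S_map, the
    Kullback-Leibler divergence between the atomistic configurational
    distribution and the distribution implied by observing the system
    through the mapping; mapent computes it exactly for discrete toy
    systems and via a variance-over-macrostates estimator for sampled
    ensembles. A deep graph-network surrogate (an edge-weighted graph
    isomorphism network with a site-aware readout, trained with Adam on
    mean absolute error) predicts S_map from the graph alone, and two
    enhanced-sampling engines operate on the combinatorial space of
    fixed-cardinality atom subsets: simulated annealing with exponential
    cooling for minimization, and Wang-Landau flat-histogram sampling for
    reconstruction of the density of states of S_map. A synthetic module
    generates toy structures, analytic scoring oracles and discrete
    ensembles so that the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
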