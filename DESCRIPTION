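Package: barrierbench
Title: Benchmarking Genetic Boundary Detection on Simulated Landscapes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A spatially explicit forward-time landscape-genetics simulator
    (lattice of diploid hermaphrodites, bivariate-normal dispersal,
    infinite-alleles mutation) with imposable, optionally permeable barriers
    to gene flow, together with two direct edge-detection methods --
    Monmonier's maximum-difference algorithm on a Delaunay triangulation and
    individual-based wombling with a binomial significance test -- and an
    evaluation protocol that scores boundary-detection correctness across
    parameter combinations, time points and replicates. Includes diversity,
    differentiation (Weir-Cockerham FST) and isolation-by-distance
    descriptors, closed-form mutation-drift equilibrium expectations, and
    readers/writers for Genepop, STRUCTURE and cluster-membership (Q-matrix)
    files so that externally produced clustering results can be scored with
    the same protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deldir,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
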