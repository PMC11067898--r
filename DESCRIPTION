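Package: nichellipse
Title: Ellipsoid Niche Models, Background Equivalency Tests and Ancestral
    Niche Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying ecological niche evolution in allopatric
    radiations. Fits minimum volume ellipsoid niche models in environmental
    space, derives Mahalanobis-distance suitability surfaces with
    Gamma-quantile binary thresholds, runs background-similarity niche
    equivalency tests (Schoener's D against null models drawn from each
    species' accessible area, scored on a -2..+2 divergence/conservatism
    scale), clusters occurrence records into ecopopulations (linear
    discriminants, k-means, gap statistic), and reconstructs ancestral
    niches per environmental bin by parsimony on a phylogeny, conditioning
    presence, absence and uncertainty on each species' accessible area.
    Includes a virtual-species simulator that generates environmental
    rasters, trees, true ellipsoid niches under partitioning, conservatism
    and divergence scenarios, accessible-area polygons and occurrence
    samples with known ground truth, so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    fitdistrplus,
    geosphere,
    jsonlite,
    MASS,
    phytools,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    cluster,
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
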