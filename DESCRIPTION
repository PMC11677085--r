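Package: assemblyscope
Title: Phylogenetic Null Models, Interdomain Networks and Path Models for
    Microbial Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the ecological processes that assemble microbial
    communities across environmental gradients. Implements abundance-weighted
    beta mean nearest taxon distance (betaMNTD) and its standardized effect
    size (betaNTI) under a tip-shuffling phylogenetic null, the
    abundance-based Raup-Crick metric on Bray-Curtis dissimilarity (RC-bray),
    and the five-way classification of pairwise assembly processes
    (heterogeneous selection, homogeneous selection, dispersal limitation,
    homogenizing dispersal, undominated). Around that core it provides
    alpha/phylogenetic diversity and ordination wrappers, interdomain
    (bipartite) Spearman co-occurrence networks with positive-to-negative
    edge ratios and node-removal robustness, random-forest identification of
    depth-discriminating taxa with cross-validated refinement and a
    taxa-removal perturbation of the null model, partial least squares path
    modeling (PLS-PM) linking environment and biotic interaction to assembly
    determinism, and a synthetic multi-domain community generator with known
    assembly regimes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    picante,
    igraph,
    randomForest,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
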