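Package: coocnet
Title: Assembly Rules from Species Co-Occurrence Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds positive species co-occurrence networks from site-by-species
    presence-absence data with the exact pairwise hypergeometric model,
    characterises their modular and nested structure against fixed-marginal
    (degree-preserving) permutation nulls, scores the contribution of every
    species to that structure by a knock-out standardized effect size, tests
    functional and phylogenetic assembly rules (convergence, divergence,
    neutrality) within each network module, and contrasts the results with
    abundance-based functional/phylogenetic dispersion nulls and RDA-based
    variance partitioning of Hellinger-transformed abundances over agricultural,
    soil and spatial predictor sets. A synthetic-data generator emulating a
    two-guild (plant and orthopteran) grassland survey provides ground-truth
    test beds for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    igraph,
    vegan,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Network, GraphAndNetwork, Metagenomics
Collate: 
    'coocnet-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'abundance.R'
    'cooccurrence.R'
    'structure.R'
    'assembly.R'
    'distances.R'
    'io.R'
    'nulls.R'
    'utils.R'
    'synthetic.R'
    'pipeline.R'
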