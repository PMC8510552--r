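Package: otuassembly
Title: Community Assembly Processes and Co-Occurrence Networks for OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the ecological processes that assemble microbial
    communities (selection, dispersal limitation, homogenizing dispersal and
    drift) from OTU count tables and a phylogeny, using the beta mean nearest
    taxon distance (betaMNTD), its tip-shuffled standardization (betaNTI) and
    abundance-based Raup-Crick null models.  Fits the Sloan neutral community
    model, computes Levins' niche breadth, tests phylogenetic signal in OTU
    niches with Mantel correlograms, provides distance-matrix statistics
    (Mantel, partial Mantel, multiple regression on distance matrices,
    variation partitioning) and builds SparCC co-occurrence networks with
    topology summaries and within-module degree / participation-coefficient
    node roles.  Includes a synthetic-data generator with known ground truth
    (birth-death trees, Brownian niche traits, environmental filtering and
    spatial dispersal kernels) so every stage of the pipeline can be
    validated against simulated communities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
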