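Package: divscape
Title: Spatial Mapping of Mitochondrial Genetic Diversity with AMOVA and
    Distribution-Model Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape-scale analyses of mitochondrial sequence
    variation in georeferenced samples, built around the workflow used for
    Iberian semi-aquatic mammals: collapsing putative repeat samples of one
    individual with an identical-haplotype minimum-distance rule, stripping
    gap positions and concatenating gene partitions with missing-data
    padding, core population-genetic estimators (nucleotide diversity,
    Watterson's theta, haplotype diversity, p-distances), phylogroup-aware
    moving-window nucleotide-diversity maps, one-way analysis of molecular
    variance (AMOVA) by river basin with a permutation null, and
    percentile-threshold consensus post-processing of habitat-suitability
    rasters. A coalescent-based synthetic-data generator emulates a
    two-phylogroup landscape with contact zones so every stage can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
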