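Package: sedarch
Title: Catalog Accounting, Community Ecology, and Divergence-Time
    Classification for Plateau Sediment Metagenomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytical layer for large sediment metagenome catalogs:
    MAG quality scoring and MIMAG tiering, species novelty and
    exclusivity accounting, gene rarefaction, distance-decay and Sloan
    neutral-community-model fitting, classification of possible ancient
    species on time-calibrated phylogenies with relative evolutionary
    distance, biosynthetic gene cluster (GCF/GCC) novelty rules, a
    per-Mb KO enrichment-ratio statistic, and sliding-window
    oligonucleotide probe specificity screening.  Includes seeded
    synthetic-data generators with planted, recoverable ground truth
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    geosphere,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    vegan
Suggests:
    mclust,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
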