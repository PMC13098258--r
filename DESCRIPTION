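Package: magun
Title: Genome Units and Within-Species Diversity in MAG Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-resolved analysis of metagenome-assembled genome (MAG)
    collections from population cohorts. Estimates pairwise average
    nucleotide identity (ANI) by canonical k-mer MinHash sketching,
    partitions MAGs into species clusters (95% ANI) with nested genome
    units (99% ANI), scores and selects representative genomes, merges a
    cohort-specific collection with a public reference, classifies MAGs
    into MIMAG quality tiers, and computes the genome unit number (GUN)
    and its normalized form (nGUN) to quantify within-species diversity.
    Includes species-level association testing on centered log-ratio
    transformed abundances, genome-unit presence/absence logistic
    association models, and a fully synthetic cohort generator with
    planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
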