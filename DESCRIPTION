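Package: mitoRates
Title: Comparative Analysis of Mitogenomic Evolutionary Rates Across
    Life-History and Locomotory-Capacity Categories
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how parasitic life history and locomotory
    capacity shape mitochondrial evolutionary rates across animals. The
    package curates mitogenome records (gene-name standardisation,
    stop-codon and conservation based resolution of duplicated
    protein-coding genes, dataset filters), extracts per-species
    root-to-tip branch lengths from a phylogram as rate proxies,
    reconstructs ancestral discrete states under Mk models by maximum
    likelihood, and partitions rate variance with phylogeny-aware
    statistics: PGLS, a kinship-based phylogenetic linear mixed model,
    likelihood-ratio R-squared, AIC and chi-square likelihood-ratio
    tests, Tukey HSD with compact letter displays, Cohen's d and power.
    A seeded synthetic-data generator (Yule chronograms, Mk trait
    histories, state-dependent branch-rate multipliers, toy GenBank
    records) supports end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    Matrix,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    optparse
Config/testthat/edition: 3
biocViews: Phylogenetics, Genetics, Software, StatisticalMethod
RoxygenNote: 7.3.3
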