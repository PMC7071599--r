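Package: sagescape
Title: Simulation and Analysis of Multiplexed deepSAGE Expression Profiles
Version: 0.1.0
Authors@R:
    person("sagescape", "developers", email = "sagescape@example.org",
           role = c("aut", "cre"))
Description: Tools for tag-based serial analysis of gene expression (SAGE)
    profiling with multiplexed deep sequencing. Simulates SAGE libraries
    (NlaIII-anchored 19 bp tags cut by EcoP15I, barcoded multiplex reads),
    builds virtual tag references from transcript FASTA, demultiplexes and
    quality-filters reads, extracts and counts tags with multi-mapping
    averaging and quantile normalization, and provides the downstream
    statistics used for tissue expression atlases: rarefaction curves,
    principal component analysis with iterative sample exclusion, moderated-t
    tissue-specific expression calling, bootstrap-refined (BF98) K-means
    clustering with hierarchical substructure, and Clover-style position
    weight matrix over-representation with randomization p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
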