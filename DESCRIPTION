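Package: megascreen
Title: Identity-Based Clade Delimitation, Chimera Screening, OTU Ecology
    and Probe Design for 16S rRNA Endosymbiont Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for characterizing the diversity and
    environmental distribution of a bacterial endosymbiont genus from 16S
    rRNA gene data. Provides pairwise-identity species-level clade
    delimitation by single-linkage clustering, split-and-compare chimera
    screening with breakpoint localization, hypervariable-region mapping of
    short amplicons, greedy centroid OTU clustering with environment
    attribution, frequency-of-occurrence and relative-abundance ecology
    indices, neighbor-joining region trees, and clade-specific
    hybridization-probe design with in-silico 0/1-mismatch specificity
    checking and GC-based melting temperatures. A fully ground-truthed
    synthetic-data generator emulates clade-structured genera, chimeras and
    environment-labelled amplicon samples so every stage is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    ape,
    yaml,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
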