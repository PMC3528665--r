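Package: haloriscan
Title: Prediction and Evolutionary Classification of orc/cdc6-Associated
    Replication Origins in Haloarchaeal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate replication origins adjacent to orc/cdc6
    replication-initiator genes in multi-replicon haloarchaeal genomes.
    Screens proteomes for origin-associated Orc/Cdc6 homologs, extracts
    flanking intergenic regions, discovers ORB (origin recognition box)
    motifs with a ZOOPS expectation-maximization model, detects the
    halophile-specific terminal G-string and AT-rich unwinding elements,
    classifies each initiator locus as a candidate, deficient, dual or
    absent origin, clusters origins into families by initiator identity,
    builds neighbor-joining initiator phylogenies, and flags origins with
    nearby mobile elements as likely later acquisitions. A synthetic
    genome generator with planted ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
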