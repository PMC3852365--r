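Package: copiascan
Title: Simulation, Discovery and Marker Development for Copia-Type LTR
    Retrotransposon Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully in-silico re-implementation of a classic
    PCR-based workflow for characterizing copia-type LTR retrotransposon
    families in a plant genome: degenerate-primer in-silico PCR against the
    reverse-transcriptase (RT) domain, neighbor-joining classification of RT
    clones into families, seeded local-alignment homology search, iterative
    consensus extension to full-length elements, structural annotation (LTR
    pair, PBS, PPT, GAG-POL ORF, TSD, restriction map), genomic-context
    profiling of element flanks, and design plus in-silico genotyping of
    retrotransposon-based insertion polymorphism (RBIP) markers.  A synthetic
    genome generator with exact ground truth (implanted element copies, gene
    tracks, accession panels) supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
SystemRequirements: mafft (for multiple peptide alignment)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
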