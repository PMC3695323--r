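Package: stowawaykit
Title: Discovery, Classification and Genotyping of Stowaway-Like MITEs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying Stowaway-like miniature inverted-repeat
    transposable elements (MITEs) in plant genomes: a structural miner that
    locates candidates by their TA target-site duplications and CTCCCT-type
    terminal inverted repeats, a homology search with BAC-end-style
    validation filters, 80-80-80 family classification with Kimura
    two-parameter distances and Neighbor-Joining trees, BAC-screen copy
    number estimation (naive and Poisson-corrected), nested-insertion
    decomposition, insertion-site polymorphism genotyping with in-silico
    PCR, and a synthetic-genome simulator that plants elements with full
    ground truth so every stage can be benchmarked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
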