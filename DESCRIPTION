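Package: tepoly
Type: Package
Title: Comparative Detection of Species-Specific Transposable Element
    Insertions Between Closely Related Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects transposable element (TE) insertion polymorphisms
    between two closely related genome sequence sets by annotating TE
    copies against a consensus library, establishing orthologous
    fragments by anchor chaining, pairing annotations "face to face"
    across the orthology map, and calling species-specific insertions at
    filled-versus-empty sites with automated boundary refinement.
    Structural characterization covers target site duplications, long
    terminal repeats (LTRs), solo-LTR recombination events, composite
    insertions, copy number and transcriptome representation, and
    high-identity subfamily clustering. Headline divergence statistics
    (insertion densities, per-species base-pair contributions,
    genome-wide extrapolations) are computed and rendered as reports. A
    synthetic genome-pair simulator with a ground-truth manifest allows
    the whole pipeline to be exercised and scored without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
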