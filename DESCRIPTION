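Package: spliceshare
Title: Splice-Site Conservation Analysis Across Orthologous Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives coding-exon splice sites with residue/frame labels from
    gene structures, maps coding transcripts onto genomic sequence under an
    exact-match spliced model, projects splice sites of many proteins onto a
    shared protein multiple alignment, and classifies shared sites, absent
    sites and one-nucleotide shifts as evidence of common intron ancestry.
    Also scans PROSITE-style sequence signatures, scores signature windows
    within alignments, checks catalytic-residue conservation at an
    alignment-anchored reference position, and simulates orthologous gene
    families with known intron gain/loss histories on a phylogeny so the
    whole pipeline can be validated against exact truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
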