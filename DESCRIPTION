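Package: rbped
Title: RNA-Binding Protein Preference for A-to-I Edited Transcripts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies adenosine-to-inosine (A-to-I) RNA editing levels at
    catalogued sites in eCLIP and matched RNA-seq alignments or count tables,
    tests each RNA-binding protein (RBP) for global (paired Wilcoxon
    signed-rank) and per-site (Fisher exact) preference toward edited or
    unedited transcripts, builds RBP-RBP networks weighted by shared editing
    sites or by overlapping binding-peak length and compares them with a
    seeded permutation test, relates RBP-associated editing sites to
    exon/intron boundaries and differential alternative-splicing events, and
    evaluates RNA secondary-structure changes upon in-silico editing under
    PARS-derived folding constraints with a pluggable folding engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
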