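Package: mirnome
Title: Small RNA Sequencing miRNome Quantification and Novel miRNA Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested small RNA sequencing (smRNA-Seq) analysis pipeline for
    endothelial-cell miRNome profiling: read filtration (poly-A, ambiguous,
    5' adapter and adapterless read removal with 6-18 nt 3' adapter
    recognition), collapsing of identical inserts to unique tags, exact-match
    genome placement with mRNA exclusion and known-miRNA annotation,
    multi-mapping-corrected RPM quantification (C/(MN) x 10^9), >=1.5-fold
    differential signature calling, consensus novel-miRNA discovery with
    Nussinov hairpin folding and Ago1/2 RIP-seq verification, signature
    overlap statistics and a running-sum (GSEA-style) enrichment test with a
    permutation null. Ships a seeded synthetic-data generator that plants
    known and novel miRNA hairpins in a toy genome with known ground truth,
    plus transcriptions of published fold-change tables and a consistency
    checker for them.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
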