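Package: baitquant
Title: Exon-Junction Quantification from Junction-Spanning RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies alternative splicing events (exon skipping and
    alternative 3' splice-acceptor usage) from single-end RNA-Seq reads by
    exact matching against fixed-length junction bait sequences, following the
    bait-BLAST strategy used for developmental profiling of Fmr1 transcripts.
    Provides a gene model for multi-exon genes with optional exons and
    multi-acceptor exons, transcript enumeration and splicing, ORF and
    premature-termination-codon annotation, a seeded single-end read simulator
    with stage-specific isoform profiles, a full-identity matcher with
    Karlin-Altschul E-value window filtering and per-bait retrieval caps, RPKM
    normalization, splice-site usage ratios, robust outlier exclusion, and
    tie-corrected Kruskal-Wallis tests with Dunn's post-hoc pairwise stage
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
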