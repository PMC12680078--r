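Package: pepgraph
Title: Graph-Based Enumeration of Non-Canonical Peptides for Proteogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sample-specific non-canonical peptide databases for
    proteogenomic mass-spectrometry searches. Genomic and transcriptomic
    variants (SNVs, small indels, RNA editing, alternative splicing, gene
    fusions and circular RNAs) are projected into transcript coordinates and
    woven into a transcript variant graph with explicit three-reading-frame
    modeling, so that every compatible variant combination -- including
    frameshift cascades -- is enumerated in time linear in the number of
    variants. The graph is translated, partitioned at enzymatic cleavage
    sites and traversed to call variant peptides, novel-ORF peptides from
    noncoding transcripts, circular-RNA read-through peptides and
    alternative-translation products, excluding anything producible from the
    canonical proteome. A brute-force enumeration oracle and a fuzz-testing
    simulator are included for validation, together with target-decoy FDR
    helpers for downstream search results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    S4Vectors,
    GenomicRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
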