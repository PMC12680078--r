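# pepgraph

Graph-based enumeration of non-canonical peptides for proteogenomics.

## The problem

Searching tandem mass spectra against a sample-specific peptide database
requires predicting every peptide the sample's genome and transcriptome
could produce: single-nucleotide variants, small indels, RNA editing,
alternative splicing, gene fusions and circular RNAs — and, crucially,
their **combinations** on the same transcript. Enumerating combinations
naively is exponential in the number of variants; pepgraph does it in
time linear in the number of variant sites by working on a sequence
graph.

For each transcript backbone the package builds a **transcript variant
graph** with all three reading frames modeled explicitly (frame chain
*k* holds the sequence offset *k* nt from the 5′ end). A variant with
reference/alternative allele lengths *S*<sub>ref</sub>, *S*<sub>alt</sub>
entering in frame *f* closes into frame

> *f*<sub>out</sub> = (*f* + *S*<sub>ref</sub> − *S*<sub>alt</sub>) mod 3,

so frameshift cascades are ordinary graph edges. Overlapping variants
are aligned into **variant bubbles** (one member path per compatible
variant subset) between connection nodes, member lengths are adjusted to
codon boundaries, the graph is translated, partitioned at enzymatic
cleavage sites into a **peptide cleavage graph**, and traversed with a
stage-and-call discipline that resolves each node's open reading frames
before emitting peptides with up to the permitted number of
miscleavages. Peptides producible by the canonical proteome are removed;
the rest are deduplicated with all their (gene, backbone, variant
combination, ORF) sources and split into tiers (Variant, Noncoding,
NoncodingVariant, CircularRNA, AltTranslation). Fusion transcripts and
circular RNAs (with rolling read-through across the back-splice
junction, up to three traversals) are handled as novel backbones, and
alternative-translation products (selenocysteine-termination isoforms,
tryptophan-to-phenylalanine substitutants) round out the database.

A **brute-force oracle** (`brute_force_peptides()`) and a **fuzz-testing
simulator** (`simulate_case()`, `fuzz_run()`) are part of the package:
the oracle enumerates all compatible variant subsets by string editing
and is the ground truth the graph pipeline is validated against.

## Worked example

A one-exon coding transcript with a somatic SNV (D→H at the protein
level):

```r
library(pepgraph)

seq <- paste0("ATG", "GATCCGATTAAGCGCGGG", "AAACCCTTTGATGAGCATTTC",
              "AAGGAGATCGAC", "TGA")
model <- transcript_model("TX1", "GENE1", "chr1", "+",
                          exons = cbind(0L, nchar(seq)),
                          cds_start_tx = 0L,
                          cds_end_tx = nchar(seq) - 3L)
v <- variant_table("chr1:31:G>C", "GENE1", "TX1", 30L, 31L,
                   substr(seq, 31, 31), "C", "SNV", "sSNV")
canonical <- canonical_digest_set(c(P1 = translate_nt(seq)),
                                  call_params(min_length = 5L))
call_variant_peptides(seq, model, v, call_params(min_length = 5L),
                      canonical_digest = canonical,
                      gene_id = "GENE1", backbone_id = "TX1")
#>           peptide    tier gene_id backbone_id variant_ids miscleavages
#> 1 MDPIKRGKPFHEHFK Variant   GENE1         TX1 chr1:31:G>C            2
#> 2      RGKPFHEHFK Variant   GENE1         TX1 chr1:31:G>C            1
#> 3   RGKPFHEHFKEID Variant   GENE1         TX1 chr1:31:G>C            2
#> 4       GKPFHEHFK Variant   GENE1         TX1 chr1:31:G>C            0
#> 5    GKPFHEHFKEID Variant   GENE1         TX1 chr1:31:G>C            1
```

The canonical protein is `MDPIKRGKPFDEHFKEID`; every reported tryptic
peptide covers the variant residue (D→H), satisfies the length bound
(here ≥ 5 for the toy example; the production default is 7–25 with two
miscleavages), and cannot be produced by digesting the canonical
proteome. `dedupe_and_annotate()`, `split_tiers()` and
`write_peptide_fasta()` turn entries from many backbones into tiered
FASTA databases; `exec/pepgraph` exposes the same steps as a command
line (parseVEP, parseFusion, parseAltSplice, parseRNAEditing,
parseCircRNA, callVariant, callNovelORF, callAltTranslation, mergeDB,
splitDB, fuzz, fdr).

See `vignettes/pepgraph-methods.Rmd` for the model, the biological
edge-case rules (start-codon and splice-site variants are excluded,
stop-loss does not read past the transcript), the pop-and-collapse bound
on hypermutated bubbles, and the circular-RNA semantics.

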