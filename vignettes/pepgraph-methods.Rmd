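---
title: "pepgraph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepgraph: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepgraph)
```

## The problem

Sample-specific proteogenomics searches tandem-MS spectra against a
database of peptides the sample could actually produce. Building that
database means modeling how genomic and transcriptomic variation changes
protein sequence: point mutations, small indels, RNA editing, alternative
splicing, gene fusions and RNA circularization, **in combination**. The
number of haplotype-level sequence versions grows exponentially with the
number of variants on a transcript, so naive enumeration (apply every
compatible variant subset, translate, digest) is infeasible beyond a
handful of variants. pepgraph enumerates the same peptide set on a
sequence graph, where work is proportional to the number of variant sites
rather than the number of their combinations.

## The three graph stages

**Transcript variant graph (TVG).** For each transcript backbone the
graph starts as three linear chains holding the transcript sequence
offset by 0, 1 and 2 nt from the 5' end — one chain per reading frame. A
variant is incorporated by breaking the chain at the variant's start and
end and attaching a node with the alternative sequence. An in-frame
variant closes back into its own chain; a frameshifting variant closes
into the chain of the outgoing frame

\[ f_{out} = (f_{in} + S_{ref} - S_{alt}) \bmod 3, \]

where \(S_{ref}\) and \(S_{alt}\) are the reference and alternative
allele lengths. The mod is a floor mod (insertions make the difference
negative). Because chain \(k\) trims \(k\) nt from the 5' end, its codon
grid consists of positions congruent to \(k\) modulo 3, and the
continuation of a frameshifted path lands exactly on the codon grid of
its outgoing chain — this is what makes explicit three-frame modeling
equivalent to re-translating every edited sequence. Large insertions and
substitutions from alternative splicing are subgraphs of reference-typed
nodes that can carry their own nested small variants (one level of
nesting).

For transcripts with an annotated ORF the graph is rooted at the start
codon: under the edge-case rules below no peptide can derive from the 5'
UTR, so it is dropped. All three frame chains are materialized whenever a
frameshifting variant exists (or the ORF is unknown); every variant is
then applied to every materialized chain. Parts of a chain that no ORF
can reach are simply never visited during calling, so this is equivalent
to the more parsimonious "only reachable frames" bookkeeping while making
variant application order-independent.

**Variant bubbles and the peptide variant graph (PVG).** Variant nodes
that overlap in transcript coordinates are aligned into *bubbles*
delimited by *connection nodes*: reference runs of at least five
nucleotides free of variant spans (the graph root and the transcript end
always qualify). Within a bubble, every pairwise-compatible subset of
variants — compatibility meaning disjoint reference spans — becomes one
merged member path; overlapping variants are thereby eliminated
automatically. Member boundaries are then adjusted to codon boundaries by
taking whole nucleotides from the flanking anchors (members of a
frameshifting subset end on the codon grid of their outgoing frame; they
are resolved in their own chain, never merged across frames). Each node
is then translated: stop codons are kept as `*` and resolved during
traversal, `TGA` at an annotated selenocysteine codon start becomes `U`,
and codons containing `N` become `X` (peptides containing `X` are
suppressed at output).

**Peptide cleavage graph (PCG).** The translated graph is partitioned
into segments whose interiors contain no enzymatic cleavage site and
whose edges are exactly the cleavage sites. Cleavage motifs can span node
boundaries (for example trypsin's K/P suppression and its WK/P override),
so segment discovery carries a one-residue upstream context and a
one-residue lookahead across nodes — sufficient for every supported
protease rule. Stop codons terminate segments; the residues after a stop
begin fresh, not-in-ORF segments so that downstream novel-ORF methionines
remain reachable.

**Stage-and-call.** Segments are visited after all their predecessors.
A liveness value propagated over the segment DAG records whether a
segment's start is inside an ORF (the annotated ORF for coding backbones;
for noncoding backbones any methionine in any frame chain, including
start-gain methionines inside variant nodes). Peptides are emitted from
segment starts (which are post-cleavage positions by construction), from
ORF-start methionines inside segments, and extended across at most
`max_miscleavage` downstream segments; peptide ends are cleavage sites,
stop codons, or the transcript end ("terminate at the last complete
peptide when the stop codon is unknown"). For backbones with a known ORF,
frameshift variant identifiers are carried along the segment DAG so that
downstream peptides in a shifted frame remain attributable to the variant
that caused the shift; where several frameshift routes converge the union
is recorded, which can over-attribute sources but never affects the
called sequences.

Finally, peptides producible by the canonical proteome (digested once
with identical enzyme, miscleavage and length settings) are removed,
entries are deduplicated by sequence with all (gene, backbone, variant
combination, ORF) sources retained, and the database is split into tiers
— Variant, Noncoding, NoncodingVariant, CircularRNA, AltTranslation —
with a multi-tier entry assigned to the highest-priority tier in that
order (the tie-break is this package's choice; the tier definitions fix
no order for shared peptides).

## Hypermutated regions: pop-and-collapse

Dense variant clusters make bubble member counts grow combinatorially.
When a bubble exceeds `pop_cutoff` member nodes (default 32), the last
`pop_x` residues (default 5) of each member are popped into suffix nodes
and identical suffixes are collapsed into one shared node whose variant
annotations are unioned. The callable peptide multiset is unchanged
(checked property-style in the test suite); only the node count shrinks.
The defaults are deliberately conservative — they trigger only in
hypermutated bubbles — and are exposed as parameters and CLI flags.
Member enumeration itself is additionally guarded by a hard cap (65,536
combinations) that raises an error rather than silently truncating.

## Non-canonical backbones

**Fusion transcripts.** Callers report gene pairs, so one backbone is
instantiated per donor-transcript x acceptor-transcript pair. The
backbone joins the donor sequence up to the breakpoint with the acceptor
sequence from its breakpoint on; an intronic breakpoint retains the
unspliced intron up to (donor) or from (acceptor) the breakpoint, and
intronic variants inside the retained span are mapped in. Donor variants
5' of the breakpoint and acceptor variants 3' of it are incorporated;
variants overlapping a breakpoint are dropped with a warning. The donor
ORF start is used when the donor is coding and its start codon survives
in the retained segment; otherwise the backbone is treated as noncoding.
All fusion peptides carry the fusion event among their sources.

**Circular RNAs.** A circle is read through its back-splice junction; if
its length \(L\) is not a multiple of three each traversal shifts the
frame, and after three traversals the amino-acid sequence repeats, so
each ORF is capped at \(3L\) nt from its start methionine. The circle is
linearized as four concatenated copies so that every window of up to
three traversals exists linearly; ORF starts are restricted to the first
traversal (later methionines are periodic images of first-traversal
ones). Because a circle has no physical 3' end, circular peptides must
end at a cleavage site or stop codon — never at the artificial
linearization boundary. A variant is a property of the molecule and must
be present in every traversal or none, so the caller enumerates
compatible variant subsets at the circle level and runs the linearized
rolling-ORF graph per edited circle, rather than replicating variant
bubbles per copy with independent choices (which would create
biologically impossible mixed-traversal products). circRNA variant
counts are small in practice, so this costs little.

## Biological edge-case rules

* Variants overlapping the annotated start codon are excluded: whether
  and where translation would still initiate is unknowable.
* Variants whose annotation consequence marks a splice site
  (`splice_donor/acceptor/region`) are excluded, and the small-variant
  parsers drop records whose genomic footprint touches the two intronic
  nucleotides flanking an exon.
* Stop-codon-altering variants are kept, but translation never extends
  past the transcript end (the downstream genome is not assumed to be
  transcribed); the C-terminal product is the last complete peptide.
* On coding transcripts, variants strictly 5' of the ORF or strictly 3'
  of the annotated stop codon are dropped — under the rules above they
  cannot change any called peptide.
* The annotated ORF bounds exclude the stop codon; translation discovers
  stop codons from the sequence itself, which also makes transcripts with
  incomplete 3' annotation behave sensibly.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `enzyme` | trypsin | one of trypsin, Lys-C, Lys-N, Arg-C, Glu-C, Asp-N, chymotrypsin |
| `max_miscleavage` | per enzyme (2/2/2/2/3/3/4) | maximum internal uncut sites per peptide |
| `min_length`, `max_length` | 7, 25 | reported peptide lengths (residues) |
| `pop_cutoff`, `pop_x` | 32, 5 | pop-and-collapse gating and pop size |
| `w_to_f_multi` | FALSE | multi-site W>F substitutant combinations |

The protease rules are the community-standard ones (C-side of K/R except
before proline for trypsin, with the WK/P override; C-side of K, R, E;
N-side of K, D; C-side of F/W/Y except before proline). The
low-specificity chymotrypsin variant that also cuts after L/M is *not*
included.

## The brute-force oracle and fuzz testing

`brute_force_peptides()` is the independent ground truth: it enumerates
every pairwise-compatible variant subset by bitmask, applies each subset
by string editing, translates (the known ORF, or all methionines in three
frames, or the circular rotation windows), digests, applies the bounds
and the canonical filter, and unions the results. Its cost doubles with
every added variant, which is exactly why it can only serve as a
validation oracle at small scale (at most 20 variants per case).

Subset compatibility — disjoint reference spans, nested records only with
their parent, and zero-width insertion spans at the same position treated
as incompatible (their application order would be ambiguous) — and the
deterministic application order (descending start, then descending end)
are shared conventions between the two engines; everything else
(enumeration, translation bookkeeping, digestion traversal) is computed
by entirely different routes, which is what makes their agreement
informative.

`simulate_case()` draws transcripts (length 60–600 nt, coding with
probability 0.6, ORF position and occasional selenocysteine codon drawn
at random, 1–12 variants weighted 70% SNV / 20% indel / 10%
splicing-like events, indel lengths 1–9 nt) or fusion/circular cases,
fully reproducible from a single seed. These defaults are the simulator's
declared study conditions. The simulator emulates spliced transcript
*sequences* and variant placement honoring the edge-case rules; it does
not emulate multi-exon genomic structure in the calling path (exercised
separately through the annotation and parser tests), sequencing errors,
or variant allele frequencies — agreement on fuzz cases therefore
demonstrates algorithmic correctness of the enumeration, not caller
accuracy on real sequencing data.

The test suite runs 1,000 fuzz cases spanning SNV-only, SNV+indel,
noncoding, splicing-heavy, fusion and circRNA configurations and requires
100% agreement; it also fits pipeline runtime against variant count
(10–200 variants at constant variant density, one SNV per 50 nt, with
per-size medians of three replicates after a warm-up run) and requires
\(R^2 \ge 0.95\) for a linear fit, while verifying that the brute-force
subset count doubles per added variant. Problem sizes throughout the
suite (case counts, replicate counts, sequence lengths) are chosen to
exercise every code path at desk scale; `scripts/acceptance.R` recomputes
the same quantities end to end.

## FDR helpers

Peptide-level target-decoy FDR is \((D + 1)/(T + D)\) for decoy and
target PSM counts, clipped to 1 (the formula exceeds 1 when targets are
scarce; the clip is this package's choice). The post hoc cohort-level
cutoff finds, per sample, the target hit with the highest FDR under the
per-sample threshold (\(FDR_i\)), tallies decoy and target hits at or
below it, and divides total decoys by total hits across the cohort.
Samples with no sub-threshold target hit contribute nothing.

## Numerical and representational choices

* All coordinates are 0-based half-open; GTF input is converted on
  ingestion. Transcript coordinates live in spliced-transcript space on
  the transcript's own strand.
* Indels are stored VCF-style, left-anchored with one reference base
  retained, which keeps bubble construction unambiguous; the
  alternative-splicing parser emits anchor-free insertions/deletions with
  the event's own span.
* The GVF dialect is tab-separated with VCF-like columns (gene ID in
  CHROM, 1-based transcript start in POS, `TRANSCRIPT=`, `TYPE=`,
  `SOURCE=`, optional `PARENT=`/`CONSEQUENCE=` in INFO); records are
  ordered by (gene, start, alt, id) so a second write is byte-identical.
* Codon-boundary adjustment takes the 0–2 nt dictated by each frame's
  codon grid from the anchors; anchors shorter than the connection
  threshold never arise because such runs never become connection nodes
  in the first place (bubbles simply extend across them — the
  "swallow-and-merge" behavior).
* Mutually exclusive exons are modeled as substitutions of one exon's
  sequence by the other's; retained introns and alternative 3'/5' sites
  as insertions at the splice junction; skipped exons as deletions.
* FASTA output is sorted by peptide sequence and the header grammar
  `>{gene}|{backbone}|{variants}|ORF{start}|{tier}` (sources
  space-joined) is lossless, so identical inputs give byte-identical
  databases.

## Known limitations

* Alternative-splicing subgraphs nest one level (a small variant inside a
  retained intron); events inside another event's insertion are rejected.
* Sources of peptides downstream of converging frameshift routes may be
  over-attributed (union semantics); sequences are unaffected.
* No semi-specific or chemical cleavage, no decoy generation, no
  transcript-abundance filtering, and no structural variants beyond the
  supported classes.
* Coordinate liftover between assemblies is out of scope; inputs must
  share one assembly and annotation version.

## A worked example

```{r example}
seq <- paste0("ATG", "GATCCGATTAAGCGCGGG", "AAACCCTTTGATGAGCATTTC",
              "AAGGAGATCGAC", "TGA")
model <- transcript_model("TX1", "GENE1", "chr1", "+",
                          exons = cbind(0L, nchar(seq)),
                          cds_start_tx = 0L,
                          cds_end_tx = nchar(seq) - 3L)
v <- variant_table("chr1:31:G>C", "GENE1", "TX1", 30L, 31L,
                   substr(seq, 31, 31), "C", "SNV", "sSNV")
canonical <- canonical_digest_set(
  c(P1 = translate_nt(seq)), call_params(min_length = 5L))
call_variant_peptides(seq, model, v, call_params(min_length = 5L),
                      canonical_digest = canonical,
                      gene_id = "GENE1", backbone_id = "TX1")
```
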