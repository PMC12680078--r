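# Upstream caller-output parsers.

test_that("VEP-style SNVs resolve to transcript coordinates per strand", {
  ref <- toy_reference()
  ann <- load_annotation(ref$gtf)
  base107 <- genome_subseq(ref$genome, "chr1", 107, 108)
  alt <- setdiff(c("A", "C", "G", "T"), base107)[1]
  rows <- data.frame(chrom = "chr1", pos = 108, ref = base107, alt = alt,
                     transcript_id = c("TXP", "TXM"),
                     stringsAsFactors = FALSE)
  out <- parse_vep(rows, ann, ref$genome)
  p <- out[out$tx_id == "TXP", ]
  expect_equal(p$start, 7L)
  expect_equal(p$ref, base107)
  expect_equal(p$alt, alt)
  m <- out[out$tx_id == "TXM", ]
  # mirrored offset on the minus strand, alleles reverse-complemented
  expect_equal(m$start, genomic_to_tx(ann$TXM, 107L))
  expect_equal(m$ref, reverse_complement(base107))
  expect_equal(m$alt, reverse_complement(alt))
  # the genomic allele reconstructed from the minus-strand record matches
  expect_equal(reverse_complement(m$ref), base107)
})

test_that("anchored deletions keep the VCF padding convention", {
  ref <- toy_reference()
  ann <- load_annotation(ref$gtf)
  anchor <- genome_subseq(ref$genome, "chr1", 107, 111)
  rows <- data.frame(chrom = "chr1", pos = 108, ref = anchor,
                     alt = substr(anchor, 1, 1), transcript_id = "TXP",
                     stringsAsFactors = FALSE)
  out <- parse_vep(rows, ann, ref$genome)
  expect_equal(out$type, "DELETION")
  expect_equal(out$end - out$start, nchar(anchor))
  expect_equal(out$start, 7L)
})

test_that("mismatching or unmappable records are rejected/skipped", {
  ref <- toy_reference()
  ann <- load_annotation(ref$gtf)
  base <- genome_subseq(ref$genome, "chr1", 107, 108)
  wrong <- setdiff(c("A", "C", "G", "T"), base)[1]
  rows <- data.frame(chrom = "chr1", pos = 108, ref = wrong, alt = base,
                     transcript_id = "TXP", stringsAsFactors = FALSE)
  expect_warning(out <- parse_vep(rows, ann, ref$genome), "rejected")
  expect_equal(nrow(out), 0)
  rows2 <- data.frame(chrom = "chr1", pos = 108, ref = base, alt = wrong,
                      transcript_id = "NOPE", stringsAsFactors = FALSE)
  expect_warning(out2 <- parse_vep(rows2, ann, ref$genome), "unknown")
  expect_equal(nrow(out2), 0)
  # intronic position for TXM (between its exons) is dropped silently
  b115 <- genome_subseq(ref$genome, "chr1", 114, 115)
  rows3 <- data.frame(chrom = "chr1", pos = 115, ref = b115,
                      alt = setdiff(c("A", "C", "G", "T"), b115)[1],
                      transcript_id = "TXM", stringsAsFactors = FALSE)
  out3 <- parse_rna_editing(rows3, ann, ref$genome)
  expect_equal(nrow(out3), 0)
})

test_that("RNA editing sites become SNV records with their own source", {
  ref <- toy_reference()
  ann <- load_annotation(ref$gtf)
  base <- genome_subseq(ref$genome, "chr1", 110, 111)
  rows <- data.frame(chrom = "chr1", pos = 111, ref = base,
                     alt = setdiff(c("A", "C", "G", "T"), base)[1],
                     transcript_id = "TXP", stringsAsFactors = FALSE)
  out <- parse_rna_editing(rows, ann, ref$genome)
  expect_equal(out$source, "RNAEditing")
  expect_equal(out$type, "SNV")
})

test_that("fusion rows expand to the donor x acceptor transcript product", {
  set.seed(9)
  chr <- rand_dna(400)
  g <- genome_assembly(chrF = chr)
  gtf_lines <- character(0)
  mk <- function(gene, tx, from, to) {
    c(paste0("chrF\ttoy\texon\t", from, "\t", to, "\t.\t+\t.\t",
             'gene_id "', gene, '"; transcript_id "', tx, '";'))
  }
  gtf <- paste(c(mk("GD", "D1", 1, 100), mk("GD", "D2", 1, 80),
                 mk("GA", "A1", 201, 300), mk("GA", "A2", 201, 260),
                 mk("GA", "A3", 221, 300)), collapse = "\n")
  ann <- load_annotation(gtf)
  rows <- data.frame(donor_gene = "GD", acceptor_gene = "GA",
                     donor_chrom = "chrF", donor_pos = 50,
                     acceptor_chrom = "chrF", acceptor_pos = 240,
                     stringsAsFactors = FALSE)
  evs <- parse_fusion(rows, ann)
  expect_length(evs, 6) # 2 donor x 3 acceptor transcripts
  expect_false(any(vapply(evs, `[[`, logical(1), "donor_bp_in_intron")))
  # absent acceptor gene drops the row
  rows2 <- rows
  rows2$acceptor_gene <- "NOPE"
  expect_warning(evs2 <- parse_fusion(rows2, ann), "absent")
  expect_length(evs2, 0)
})

test_that("intronic fusion breakpoints are flagged", {
  chr <- rand_dna(400)
  g <- genome_assembly(chrF = chr)
  gtf <- paste(c(
    paste0("chrF\ttoy\texon\t1\t50\t.\t+\t.\t",
           'gene_id "GD"; transcript_id "D1";'),
    paste0("chrF\ttoy\texon\t101\t150\t.\t+\t.\t",
           'gene_id "GD"; transcript_id "D1";'),
    paste0("chrF\ttoy\texon\t201\t300\t.\t+\t.\t",
           'gene_id "GA"; transcript_id "A1";')
  ), collapse = "\n")
  ann <- load_annotation(gtf)
  rows <- data.frame(donor_gene = "GD", acceptor_gene = "GA",
                     donor_chrom = "chrF", donor_pos = 75,
                     acceptor_chrom = "chrF", acceptor_pos = 240,
                     stringsAsFactors = FALSE)
  evs <- parse_fusion(rows, ann)
  expect_length(evs, 1)
  expect_true(evs[[1]]$donor_bp_in_intron)
  expect_false(evs[[1]]$acceptor_bp_in_intron)
})

test_that("alternative-splicing events become indel/substitution records", {
  set.seed(13)
  chr <- rand_dna(600)
  g <- genome_assembly(chrS = chr)
  gtf <- paste(c(
    paste0("chrS\ttoy\texon\t1\t90\t.\t+\t.\t",
           'gene_id "GS"; transcript_id "S1";'),
    paste0("chrS\ttoy\texon\t181\t300\t.\t+\t.\t",
           'gene_id "GS"; transcript_id "S1";'),
    paste0("chrS\ttoy\texon\t401\t460\t.\t+\t.\t",
           'gene_id "GS"; transcript_id "S1";')
  ), collapse = "\n")
  ann <- load_annotation(gtf)
  # retained intron of length 90 between exons 1 and 2
  ri <- data.frame(event_type = "RI", gene_id = "GS", chrom = "chrS",
                   exon_start = 90L, exon_end = 180L,
                   alt_start = NA, alt_end = NA, stringsAsFactors = FALSE)
  out <- parse_alt_splicing(ri, ann, g)
  expect_equal(out$type, "ALT_SPLICE_RI")
  expect_equal(nchar(out$ref), 0L)
  expect_equal(nchar(out$alt), 90L)
  expect_equal(out$start, 90L) # inserted at the spliced junction
  # skipped exon of length 120 -> pure deletion
  se <- data.frame(event_type = "SE", gene_id = "GS", chrom = "chrS",
                   exon_start = 180L, exon_end = 300L,
                   alt_start = NA, alt_end = NA, stringsAsFactors = FALSE)
  out2 <- parse_alt_splicing(se, ann, g)
  expect_equal(nchar(out2$ref), 120L)
  expect_equal(nchar(out2$alt), 0L)
  # A5SS extending the first exon by 10 nt
  a5 <- data.frame(event_type = "A5SS", gene_id = "GS", chrom = "chrS",
                   exon_start = 0L, exon_end = 90L,
                   alt_start = 0L, alt_end = 100L, stringsAsFactors = FALSE)
  out3 <- parse_alt_splicing(a5, ann, g)
  expect_equal(nchar(out3$alt), 10L)
  expect_equal(out3$alt, genome_subseq(g, "chrS", 90, 100))
  expect_equal(out3$start, 90L)
  # un-reconcilable coordinates are dropped with a warning
  bad <- data.frame(event_type = "SE", gene_id = "GS", chrom = "chrS",
                    exon_start = 5L, exon_end = 50L,
                    alt_start = NA, alt_end = NA, stringsAsFactors = FALSE)
  expect_warning(out4 <- parse_alt_splicing(bad, ann, g),
                 "not reconcilable")
  expect_equal(nrow(out4), 0)
})

test_that("circRNA spans map to transcript-space segments", {
  chr <- rand_dna(600)
  g <- genome_assembly(chrS = chr)
  gtf <- paste(c(
    paste0("chrS\ttoy\texon\t1\t90\t.\t+\t.\t",
           'gene_id "GS"; transcript_id "S1";'),
    paste0("chrS\ttoy\texon\t181\t300\t.\t+\t.\t",
           'gene_id "GS"; transcript_id "S1";')
  ), collapse = "\n")
  ann <- load_annotation(gtf)
  rows <- data.frame(gene_id = "GS", chrom = "chrS", start = 30L,
                     end = 240L, stringsAsFactors = FALSE)
  circs <- parse_circ_rna(rows, ann)
  expect_length(circs, 1)
  segs <- circs[[1]]$segments
  expect_equal(nrow(segs), 2)
  # exon pieces [30,90) and [180,240) -> tx [30,90) and [90,150)
  expect_equal(unname(segs[1, ]), c(30L, 90L))
  expect_equal(unname(segs[2, ]), c(90L, 150L))
})
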