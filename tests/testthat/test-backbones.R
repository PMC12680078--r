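# Fusion and circular RNA backbones.

test_that("a coding fusion yields chimeric junction peptides", {
  set.seed(61)
  tab <- codon_table()
  sense <- names(tab)[!tab %in% "*"]
  donor <- paste0("ATG", paste(sample(sense, 20, replace = TRUE),
                               collapse = ""))
  acceptor <- paste(sample(sense, 25, replace = TRUE), collapse = "")
  genome <- genome_assembly(chrD = donor, chrA = acceptor)
  ann <- list(
    TXD = transcript_model("TXD", "GD", "chrD", "+",
                           cbind(0L, nchar(donor)), cds_start_tx = 0L,
                           cds_end_tx = nchar(donor)),
    TXA = transcript_model("TXA", "GA", "chrA", "+",
                           cbind(0L, nchar(acceptor)))
  )
  ev <- fusion_event("TXD", "TXA", "GD", "GA", donor_bp_tx = 29L,
                     acceptor_bp_tx = 10L)
  bb <- build_fusion_backbone(ev, ann, genome)
  expect_true(bb$coding)
  fused <- paste0(substr(donor, 1, 30), substr(acceptor, 11,
                                               nchar(acceptor)))
  expect_equal(bb$seq, fused)
  ent <- call_fusion_peptides(bb, call_params(min_length = 5L))
  # the chimeric protein translated directly must contain every peptide
  prot <- translate_nt(fused)
  expect_gt(nrow(ent), 0)
  expect_true(all(vapply(ent$peptide, grepl, logical(1), x = prot,
                         fixed = TRUE)))
  expect_true(all(grepl(bb$fusion_id, ent$variant_ids, fixed = TRUE)))
  # zero-variant fusion graph reduces to direct translation (digest match)
  want <- sort(digest_protein(prot, max_mc = 2L, min_len = 5L,
                              max_len = 25L))
  expect_equal(sort(unique(ent$peptide)), want)
})

test_that("intronic donor breakpoints retain the unspliced intron", {
  set.seed(67)
  chrD <- rand_dna(200)
  chrA <- rand_dna(120)
  genome <- genome_assembly(chrD = chrD, chrA = chrA)
  ann <- list(
    TXD = transcript_model("TXD", "GD", "chrD", "+",
                           rbind(c(0L, 60L), c(100L, 160L))),
    TXA = transcript_model("TXA", "GA", "chrA", "+", cbind(0L, 120L))
  )
  ev <- fusion_event("TXD", "TXA", "GD", "GA",
                     donor_bp_genomic = 80L, acceptor_bp_tx = 20L,
                     donor_bp_in_intron = TRUE)
  # intronic SNV inside the retained span [60, 81)
  gv <- data.frame(variant_id = "IV1", chrom = "chrD", pos = 70L,
                   ref = substr(chrD, 71, 71), alt = "A",
                   stringsAsFactors = FALSE)
  gv$alt <- setdiff(c("A", "C", "G", "T"), gv$ref)[1]
  bb <- build_fusion_backbone(ev, ann, genome, genomic_variants = gv)
  expected_seq <- paste0(substr(chrD, 1, 60), substr(chrD, 61, 81),
                         substr(chrA, 21, 120))
  expect_equal(bb$seq, expected_seq)
  expect_equal(nrow(bb$variants), 1L)
  # the mapped intronic variant points at the same base
  v <- bb$variants[1, ]
  expect_equal(substr(bb$seq, v$start + 1, v$end), v$ref)
  expect_equal(v$start, 70L) # 60 exonic + (70 - 60) into the intron
})

test_that("noncoding donors make the fusion a novel-ORF backbone", {
  set.seed(71)
  donor <- rand_dna(80)
  acceptor <- rand_dna(90)
  genome <- genome_assembly(chrD = donor, chrA = acceptor)
  ann <- list(
    TXD = transcript_model("TXD", "GD", "chrD", "+", cbind(0L, 80L)),
    TXA = transcript_model("TXA", "GA", "chrA", "+", cbind(0L, 90L))
  )
  ev <- fusion_event("TXD", "TXA", "GD", "GA", donor_bp_tx = 39L,
                     acceptor_bp_tx = 10L)
  bb <- build_fusion_backbone(ev, ann, genome)
  expect_false(bb$coding)
  ent <- call_fusion_peptides(bb, call_params(min_length = 5L))
  expect_true(all(ent$tier == "NoncodingVariant"))
  # every peptide is downstream of some methionine in some frame
  if (nrow(ent)) {
    frames <- vapply(0:2, function(k) {
      translate_nt(substr(bb$seq, k + 1, nchar(bb$seq)),
                   stop_behavior = "keep_stops")
    }, character(1))
    expect_true(all(vapply(ent$peptide, function(p) {
      any(vapply(frames, function(aa) {
        hit <- regexpr(p, aa, fixed = TRUE)
        hit > 0 && grepl("M", substr(aa, 1, hit + attr(hit, "match.length") - 1))
      }, logical(1)))
    }, logical(1))))
  }
  expect_error(
    build_fusion_backbone(fusion_event("TXD", "TXA", "GD", "GA",
                                       donor_bp_tx = 200L,
                                       acceptor_bp_tx = 10L),
                          ann, genome),
    "outside gene body")
})

test_that("circular backbones roll through the junction", {
  # length 0 mod 3, one start, no stop: peptides repeat with period one
  # traversal; junction-spanning peptides appear
  circ <- "ATGGCTAAGGAT" # M A K D, 12 nt
  cm <- circ_rna_model("C1", "TX", "G", segments = rbind(c(0L, 12L)))
  bb <- build_circ_backbone(cm, circ)
  p <- call_params(min_length = 2L, max_length = 12L)
  ent <- call_circ_peptides(bb, p)
  # M A K | D M A K | D M A K | D: tryptic products across the junction
  expect_true("MAK" %in% ent$peptide)
  expect_true("DMAK" %in% ent$peptide)
  expect_true(all(ent$tier == "CircularRNA"))
  # stop codon in every frame of the first traversal: only pre-stop
  # peptides, none across the junction
  circ_stop <- "ATGAAGTAATAGTGA" # M K * in frame 0; no M elsewhere
  cm2 <- circ_rna_model("C2", "TX", "G", segments = rbind(c(0L, 15L)))
  ent2 <- call_circ_peptides(build_circ_backbone(cm2, circ_stop),
                             call_params(min_length = 2L))
  expect_setequal(ent2$peptide, "MK")
})

test_that("circle variants apply to every traversal consistently", {
  circ <- "ATGGCTAAGGAT"
  cm <- circ_rna_model("C1", "TX", "G", segments = rbind(c(0L, 12L)))
  v <- variant_table("CV1", "G", "TX", 4L, 5L, "C", "A", "SNV", "sSNV")
  bb <- build_circ_backbone(cm, circ, v)
  ent <- call_circ_peptides(bb, call_params(min_length = 2L))
  # edited circle: M D K D in every traversal; no mixed-traversal products
  expect_true("MDK" %in% ent$peptide)
  expect_true("DMDK" %in% ent$peptide)
  expect_false(any(grepl("DMAKDMDK|DMDKDMAK", ent$peptide)))
})

test_that("segment lists concatenate into the circle sequence", {
  tx_seq <- paste0(rand_dna(20), "ATGAAA", rand_dna(10), "GGGTTT",
                   rand_dna(20))
  cm <- circ_rna_model("C1", "TX", "G",
                       segments = rbind(c(20L, 26L), c(36L, 42L)))
  bb <- build_circ_backbone(cm, tx_seq)
  expect_equal(bb$seq, "ATGAAAGGGTTT")
  # a variant inside the second segment maps into circle coordinates
  v <- variant_table("CV1", "G", "TX", 38L, 39L, "G", "A", "SNV", "sSNV")
  bb2 <- build_circ_backbone(cm, tx_seq, v)
  expect_equal(bb2$variants$start, 8L)
})
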