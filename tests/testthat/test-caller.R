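# Peptide calling: ORF resolution, annotation, canonical exclusion,
# tiers, alternative translation, FASTA output.

test_that("variant peptides carry exactly their variant annotations", {
  set.seed(41)
  # stop-free CDS so peptides span the whole ORF
  tab <- codon_table()
  sense <- names(tab)[!tab %in% c("*")]
  seq <- paste0("ATG", paste(sample(sense, 30, replace = TRUE),
                             collapse = ""))
  model <- seq_model(seq, cds_start = 0L)
  b <- substr(seq, 46, 46)
  v <- snv("V1", 45L, b, setdiff(c("A", "C", "G", "T"), b)[1])
  canon <- canonical_digest_set(c(P1 = translate_nt(seq)), call_params())
  ent <- call_variant_peptides(seq, model, v, call_params(),
                               canonical_digest = canon)
  expect_true(all(ent$n_variants >= 1L | !nzchar(ent$variant_ids)))
  expect_true(all(grepl("V1", ent$variant_ids)))
  expect_true(all(ent$tier == "Variant"))
})

test_that("frameshift context is carried to downstream peptides", {
  set.seed(43)
  tab <- codon_table()
  sense <- names(tab)[!tab %in% c("*")]
  body <- paste(sample(sense, 40, replace = TRUE), collapse = "")
  seq <- paste0("ATG", body)
  model <- seq_model(seq, cds_start = 0L)
  # 1-nt deletion (anchored) induces a frameshift
  ref2 <- substr(seq, 31, 32)
  v <- variant_table("FS1", "GENE", "TX", 30L, 32L, ref2,
                     substr(ref2, 1, 1), "DELETION", "sIndel")
  canon <- canonical_digest_set(c(P1 = translate_nt(seq)), call_params())
  ent <- call_variant_peptides(seq, model, v, call_params(),
                               canonical_digest = canon)
  expect_gt(nrow(ent), 0L)
  expect_true(all(grepl("FS1", ent$variant_ids)))
})

test_that("novel ORFs are found at every methionine incl. start-gains", {
  # noncoding sequence with no ATG: a start-gain SNV creates one
  # codon set chosen so no ATG can arise, within or across codons
  codons_noM_noStop <- c("GCT", "GAA", "CCG", "TTT", "GGA", "AGC")
  set.seed(47)
  seq <- paste(sample(codons_noM_noStop, 30, replace = TRUE),
               collapse = "")
  # engineer ATG via SNV: pick a GCT codon at in-frame position, turn
  # GCT -> ATG is two changes; instead place ACG and mutate A->ATG? Use
  # existing: create ATG by SNV on an "ATA" we plant
  substr(seq, 31, 33) <- "ATA"
  v <- snv("SG1", 32L, "A", "G") # ATA -> ATG start gain
  pvg <- translate_graph(seq, coding = FALSE, variants = v)
  pcg <- to_cleavage_graph(pvg, "trypsin")
  orfs <- find_novel_orfs(pcg)
  expect_gte(nrow(orfs), 1L)
  ent <- call_variant_peptides(seq, NULL, v, call_params(min_length = 5L))
  expect_true(all(grepl("SG1", ent$variant_ids)))
  # without the variant there is no M anywhere: zero peptides
  ent0 <- call_variant_peptides(seq, NULL, empty_variant_table(),
                                call_params(min_length = 5L))
  expect_equal(nrow(ent0), 0L)
})

test_that("canonical peptides are excluded from the output", {
  prot <- "MKAAAAAAAGGGGGGGK"
  stream <- data.frame(peptide = c("AAAAAAAGGGGGGGK", "AAAAAANGGGGGGGK"),
                       stringsAsFactors = FALSE)
  canon <- canonical_digest_set(c(P1 = prot),
                                call_params(min_length = 7L))
  out <- filter_canonical(stream, canon)
  expect_equal(out$peptide, "AAAAAANGGGGGGGK")
  expect_equal(nrow(filter_canonical(stream[0, , drop = FALSE], canon)),
               0L)
})

test_that("deduplication unions sources and splits tiers by priority", {
  e1 <- data.frame(peptide = "PEPTIDEK", tier = "Variant", gene_id = "G1",
                   backbone_id = "T1", variant_ids = "V1",
                   miscleavages = 0L, orf_start = "0",
                   stringsAsFactors = FALSE)
  e2 <- data.frame(peptide = "PEPTIDEK", tier = "CircularRNA",
                   gene_id = "G1", backbone_id = "C1",
                   variant_ids = "CIRC1", miscleavages = 0L,
                   orf_start = "?", stringsAsFactors = FALSE)
  e3 <- data.frame(peptide = "NOVELPEPK", tier = "Noncoding",
                   gene_id = "G2", backbone_id = "T2", variant_ids = "",
                   miscleavages = 1L, orf_start = "?",
                   stringsAsFactors = FALSE)
  db <- dedupe_and_annotate(rbind(e1, e2, e3))
  expect_equal(nrow(db), 2L)
  shared <- db[db$peptide == "PEPTIDEK", ]
  expect_equal(shared$tier, "Variant") # priority over CircularRNA
  expect_equal(length(strsplit(shared$sources, " ")[[1]]), 2L)
  tiers <- split_tiers(db)
  expect_setequal(names(tiers), c("Variant", "Noncoding"))
  # merging unions sources across databases before splitting
  merged <- merge_peptide_databases(dedupe_and_annotate(e1),
                                    dedupe_and_annotate(rbind(e2, e3)))
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$tier[merged$peptide == "PEPTIDEK"], "Variant")
})

test_that("alternative translation emits Sec-truncation and W>F peptides", {
  proteome <- c(
    SEL1 = "MAAAAAAAAUGGGGGGGR",  # selenoprotein, U mid-peptide
    PW1 = "MTTTTTTKXXX",          # ignored (X)
    PW2 = "MSSSSWSSKDDDDDDR"      # W-containing tryptic peptide
  )
  proteome <- proteome[c("SEL1", "PW2")]
  p <- call_params(min_length = 7L)
  sec <- call_alt_translation(proteome, "selenocysteine_termination", p)
  expect_true("MAAAAAAAA" %in% sec$peptide)
  expect_true(all(sec$tier == "AltTranslation"))
  wf <- call_alt_translation(proteome, "w_to_f", p)
  expect_true("MSSSSFSSK" %in% wf$peptide)
  # peptides without W contribute nothing
  expect_false(any(grepl("DDDDDDR$", wf$peptide) & !grepl("F", wf$peptide)))
  expect_error(call_alt_translation(proteome, "bogus", p), "unknown")
})

test_that("peptide FASTA output is deterministic", {
  set.seed(53)
  ent <- data.frame(peptide = c("AAAAKAAR", "CCCCKCCR"),
                    tier = "Variant", gene_id = "G1", backbone_id = "T1",
                    variant_ids = c("V2;V1", "V1"), miscleavages = 0L,
                    orf_start = "0", stringsAsFactors = FALSE)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_peptide_fasta(ent, f1)
  write_peptide_fasta(ent[2:1, ], f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_true(startsWith(lines[1], ">G1|T1|"))
  expect_equal(lines[2], "AAAAKAAR")
})
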