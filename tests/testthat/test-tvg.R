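# Transcript variant graph construction and frame routing.

test_that("graph initialization creates the three frame chains", {
  tvg <- init_tvg("ATGAAA")
  frames <- vapply(tvg$roots, function(id) {
    pepgraph:::.tvg_get(tvg, id)$seq
  }, character(1))
  expect_equal(frames, c("ATGAAA", "TGAAA", "GAAA"))
  # length-1 sequence leaves frames 1 and 2 degenerate (empty)
  tvg1 <- init_tvg("A")
  frames1 <- vapply(tvg1$roots, function(id) {
    pepgraph:::.tvg_get(tvg1, id)$seq
  }, character(1))
  expect_equal(frames1, c("A", "", ""))
  expect_error(init_tvg(""), "empty")
  m <- seq_model("ATGAAAGGGTAA", cds_start = 0L)
  expect_true(init_tvg("ATGAAAGGGTAA", m)$has_known_orf)
})

test_that("outgoing frame follows the floor-mod length formula", {
  expect_equal(outgoing_frame(1, 1, 0L), 0L)
  expect_equal(outgoing_frame(2, 1, 0L), 1L)
  expect_equal(outgoing_frame(1, 3, 1L), 2L) # (1 + 1 - 3) mod 3
  expect_equal(outgoing_frame(0, 4, 2L), 1L)
  # in-frame changes always return the incoming frame
  for (f in 0:2) expect_equal(outgoing_frame(6, 3, f), f)
})

test_that("applying a variant splits the reference node around its span", {
  seq <- "ATGAAAGGG"
  tvg <- init_tvg(seq)
  apply_variant(tvg, snv("V1", 3L, "A", "G"), frames = 0L)
  nodes <- tvg$env$nodes
  ref_seqs <- vapply(Filter(function(n) n$kind == "ref" && n$frame == 0,
                            nodes), `[[`, character(1), "seq")
  expect_setequal(unname(ref_seqs), c("ATG", "A", "AAGGG"))
  alt <- Filter(function(n) n$kind == "alt", nodes)[[1]]
  expect_equal(alt$seq, "G")
  expect_equal(alt$variant_id, "V1")
  expect_equal(reference_path_sequence(tvg, 0), seq)
})

test_that("variants on unknown-ORF transcripts appear in all frames", {
  tvg <- init_tvg("ATGAAAGGGCCC")
  apply_variant(tvg, snv("V1", 5L, "A", "T"))
  alts <- Filter(function(n) n$kind == "alt", tvg$env$nodes)
  expect_equal(sort(unname(vapply(alts, `[[`, integer(1), "frame"))), 0:2)
})

test_that("node splitting conserves the reference path in every frame", {
  set.seed(21)
  seq <- rand_dna(90)
  tvg <- init_tvg(seq)
  pos <- sort(sample(5:80, 4))
  for (i in seq_along(pos)) {
    b <- substr(seq, pos[i] + 1, pos[i] + 1)
    apply_variant(tvg, snv(paste0("V", i), pos[i], b,
                           setdiff(c("A", "C", "G", "T"), b)[1]))
  }
  for (f in 0:2) {
    expect_equal(reference_path_sequence(tvg, f),
                 substr(seq, f + 1, nchar(seq)))
  }
})

test_that("variant application is order-independent for disjoint variants", {
  seq <- rand_dna(60)
  vs <- list(snv("A", 10L, substr(seq, 11, 11), "A"),
             snv("B", 30L, substr(seq, 31, 31), "C"),
             snv("C", 50L, substr(seq, 51, 51), "G"))
  vs[[1]]$alt <- setdiff(c("A", "C", "G", "T"), vs[[1]]$ref)[1]
  vs[[2]]$alt <- setdiff(c("A", "C", "G", "T"), vs[[2]]$ref)[1]
  vs[[3]]$alt <- setdiff(c("A", "C", "G", "T"), vs[[3]]$ref)[1]
  sig <- function(order) {
    tvg <- init_tvg(seq)
    for (i in order) apply_variant(tvg, vs[[i]])
    nodes <- tvg$env$nodes
    keys <- vapply(nodes, function(n) {
      paste(n$kind, n$frame, n$seq, n$start, n$end, sep = "|")
    }, character(1))
    sort(unname(keys))
  }
  expect_equal(sig(1:3), sig(3:1))
  expect_equal(sig(c(2, 1, 3)), sig(1:3))
})

test_that("edge-case variants are excluded with reasons", {
  seq <- paste0(strrep("T", 12), "ATG", strrep("ACGGAC", 20), "TAA",
                strrep("C", 12))
  m <- transcript_model("TX", "GENE", "chr1", "+",
                        cbind(0L, nchar(seq)), cds_start_tx = 12L,
                        cds_end_tx = 12L + 3L + 120L)
  start_hit <- snv("S1", 13L, "T", "A")
  mid <- snv("S2", 60L, substr(seq, 61, 61), "A")
  mid$alt <- setdiff(c("A", "C", "G", "T"), mid$ref)[1]
  utr5 <- snv("S3", 2L, "T", "A")
  stop_hit <- snv("S4", 135L + 1L, substr(seq, 137, 137), "G")
  stop_hit$alt <- setdiff(c("A", "C", "G", "T"), stop_hit$ref)[1]
  past <- snv("S5", nchar(seq) - 2L, substr(seq, nchar(seq) - 1,
                                            nchar(seq) - 1), "G")
  past$alt <- setdiff(c("A", "C", "G", "T"), past$ref)[1]
  spliceish <- snv("S6", 60L, substr(seq, 61, 61), "A")
  spliceish$alt <- setdiff(c("A", "C", "G", "T"), spliceish$ref)[1]
  spliceish$consequence <- "splice_donor_variant"
  spliceish$variant_id <- "S6"
  res <- exclude_edge_case_variants(
    rbind(start_hit, mid, utr5, stop_hit, past, spliceish), m)
  expect_setequal(res$kept$variant_id, c("S2", "S4"))
  ex <- res$excluded
  expect_equal(ex$reason[ex$variant_id == "S1"], "start-codon-altering")
  expect_equal(ex$reason[ex$variant_id == "S3"], "5'-of-ORF")
  expect_equal(ex$reason[ex$variant_id == "S5"], "3'-of-stop-codon")
  expect_equal(ex$reason[ex$variant_id == "S6"], "splice-site-altering")
})
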