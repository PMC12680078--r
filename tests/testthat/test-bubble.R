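# Variant bubble alignment, codon adjustment, pop-and-collapse.

test_that("connection-node search honors the 5-nt minimum", {
  seq <- rand_dna(60)
  tvg <- init_tvg(seq)
  mk <- function(id, pos) {
    b <- substr(seq, pos + 1, pos + 1)
    snv(id, pos, b, setdiff(c("A", "C", "G", "T"), b)[1])
  }
  # two variants 4 nt apart: the short reference run between them is
  # skipped and both fall into one bubble
  apply_variant(tvg, mk("V1", 10L))
  apply_variant(tvg, mk("V2", 15L))
  apply_variant(tvg, mk("V3", 40L))
  cn <- find_next_connection_node(tvg, tvg$roots[1])
  nd <- pepgraph:::.tvg_get(tvg, cn)
  expect_equal(nd$start, 16L)
  expect_gte(nd$end - nd$start, 5L)
  b <- align_bubble(tvg, tvg$roots[1], cn)
  expect_setequal(unique(unlist(lapply(b$members,
                                       function(m) m$variant_id))),
                  c("V1", "V2"))
  # no further bubbles: the sink closes the last bubble
  cn2 <- find_next_connection_node(tvg, cn)
  nd2 <- pepgraph:::.tvg_get(tvg, cn2)
  expect_equal(nd2$end, nchar(seq))
})

test_that("bubble member counts match compatible-subset enumeration", {
  seq <- rand_dna(60)
  tvg <- init_tvg(seq)
  b10 <- substr(seq, 11, 11)
  b14 <- substr(seq, 15, 15)
  apply_variant(tvg, snv("V1", 10L, b10,
                         setdiff(c("A", "C", "G", "T"), b10)[1]))
  apply_variant(tvg, snv("V2", 14L, b14,
                         setdiff(c("A", "C", "G", "T"), b14)[1]))
  cn <- find_next_connection_node(tvg, tvg$roots[1])
  b <- align_bubble(tvg, tvg$roots[1], cn)
  expect_length(b$members, 4L) # ref, V1, V2, V1+V2
  # an overlapping pair is disjoint: deletion spanning the SNV
  tvg2 <- init_tvg(seq)
  del_ref <- substr(seq, 11, 13)
  apply_variant(tvg2, variant_table("D1", "GENE", "TX", 10L, 13L, del_ref,
                                    "", "DELETION", "gIndel"))
  apply_variant(tvg2, snv("S1", 11L, substr(seq, 12, 12),
                          setdiff(c("A", "C", "G", "T"),
                                  substr(seq, 12, 12))[1]))
  cn2 <- find_next_connection_node(tvg2, tvg2$roots[1])
  b2 <- align_bubble(tvg2, tvg2$roots[1], cn2)
  expect_length(b2$members, 3L) # ref, SNV-only, deletion-only
  # single SNV -> two member paths
  tvg3 <- init_tvg(seq)
  apply_variant(tvg3, snv("V1", 10L, b10,
                          setdiff(c("A", "C", "G", "T"), b10)[1]))
  b3 <- align_bubble(tvg3, tvg3$roots[1],
                     find_next_connection_node(tvg3, tvg3$roots[1]))
  expect_length(b3$members, 2L)
})

test_that("codon adjustment yields multiple-of-three members that
           reconstruct naive string edits", {
  set.seed(31)
  for (rep in 1:20) {
    seq <- rand_dna(75)
    tvg <- init_tvg(seq)
    pos <- sort(sample(6:40, 2))
    if (diff(pos) < 2) next
    vs <- lapply(seq_along(pos), function(i) {
      b <- substr(seq, pos[i] + 1, pos[i] + 1)
      if (runif(1) < 0.5) {
        snv(paste0("V", i), pos[i], b,
            setdiff(c("A", "C", "G", "T"), b)[1])
      } else {
        variant_table(paste0("V", i), "GENE", "TX", pos[i], pos[i] + 1L,
                      b, paste0(b, rand_dna(sample(1:4, 1))),
                      "INSERTION", "gIndel")
      }
    })
    for (v in vs) apply_variant(tvg, v)
    cn <- find_next_connection_node(tvg, tvg$roots[1])
    bub <- align_bubble(tvg, tvg$roots[1], cn)
    adj <- adjust_to_codon_boundary(bub, tvg)
    for (j in seq_along(adj$nodes)) {
      node <- adj$nodes[[j]]
      if (!node$terminal) {
        expect_equal(nchar(node$nt) %% 3, 0)
      }
      # upstream anchor + member + downstream anchor equals the naive
      # string edit of the whole transcript
      mem <- bub$members[[j]]
      expected <- apply_variants_to_sequence(seq, mem)$seq
      up <- substr(seq, 1, node$nt_start)
      down_start <- node$nt_end # reference coordinate where member ends
      down <- substr(seq, down_start + 1, nchar(seq))
      expect_equal(paste0(up, node$nt, down), expected)
    }
  }
})

test_that("pop-and-collapse shares identical suffixes and preserves paths", {
  mk_member <- function(seq) list(aa = seq, frame_out = 0L,
                                  terminal = FALSE,
                                  variant_ids = character(0))
  members <- list(mk_member("AAAQQ"), mk_member("CCCQQ"),
                  mk_member("DDDQQ"), mk_member("EEEQQ"))
  out <- pop_and_collapse(members, x = 2L, cutoff = 3L)
  expect_length(out$suffixes, 1L)
  expect_equal(out$suffixes[[1]]$seq, "QQ")
  expect_length(out$prefixes, 4L)
  paths <- vapply(seq_along(out$prefixes), function(i) {
    sfx <- Filter(function(s) i %in% s$members, out$suffixes)[[1]]
    paste0(out$prefixes[[i]]$aa, sfx$seq)
  }, character(1))
  expect_setequal(paths, c("AAAQQ", "CCCQQ", "DDDQQ", "EEEQQ"))
  # distinct suffixes cannot collapse
  members2 <- list(mk_member("AAAQ"), mk_member("CCCW"), mk_member("DDDY"),
                   mk_member("EEEV"))
  out2 <- pop_and_collapse(members2, x = 2L, cutoff = 3L)
  expect_length(out2$suffixes, 4L)
  # cutoff above the member count gates the operation off
  out3 <- pop_and_collapse(members, x = 2L, cutoff = 32L)
  expect_length(out3$suffixes, 0L)
  expect_equal(out3$prefixes[[1]]$aa, "AAAQQ")
  # x larger than the shortest member is reduced with a warning
  expect_warning(pop_and_collapse(list(mk_member("AB"), mk_member("CB"),
                                       mk_member("DB"), mk_member("EB")),
                                  x = 5L, cutoff = 3L), "reduced")
})
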