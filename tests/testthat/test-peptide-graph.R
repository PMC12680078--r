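# Protease rules, PVG translation, cleavage graph conversion.

test_that("trypsin K/P suppression and WK/P override", {
  expect_equal(cleavage_sites("AKPWKPR", "trypsin"), 5L)
  expect_equal(cleavage_sites("MKR", "trypsin"), 2L)
  expect_setequal(digest_protein("MKR", min_len = 1L, max_len = 5L),
                  c("MK", "R", "MKR"))
  expect_equal(cleavage_sites("AEG", "gluc"), 2L)
  expect_equal(cleavage_sites("AKDA", "aspn"), 2L) # N-side of D
  expect_equal(cleavage_sites("AKA", "lysn"), 1L)  # N-side of K
  expect_equal(sort(digest_protein("AKPWKPR", min_len = 1L,
                                   max_len = 10L, max_mc = 0L)),
               c("AKPWK", "PR"))
})

test_that("all seven proteases match a residue-scanning oracle", {
  set.seed(17)
  enzymes <- c("trypsin", "lysc", "lysn", "argc", "gluc", "aspn",
               "chymotrypsin")
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y", "U")
  for (i in 1:150) {
    s <- paste(sample(aas, sample(2:40, 1), replace = TRUE),
               collapse = "")
    e <- sample(enzymes, 1)
    expect_identical(cleavage_sites(s, e), scan_cut_sites(s, e),
                     label = paste(e, s))
  }
})

test_that("the enzyme rule table documents every protease", {
  tab <- enzyme_rule_table()
  expect_equal(nrow(tab), 7L)
  expect_true(tab$wkp_override[tab$enzyme == "trypsin"])
  expect_equal(tab$default_max_miscleavage[tab$enzyme == "chymotrypsin"],
               4L)
  expect_error(enzyme_spec("papain"), "unknown enzyme")
})

test_that("graph translation is node-wise with stop and Sec handling", {
  pvg <- translate_graph("ATGAAA", coding = TRUE)
  aas <- vapply(pvg$nodes, `[[`, character(1), "aa")
  expect_true("MK" %in% aas)
  # stop codons are kept as * and resolved during traversal
  pvg2 <- translate_graph("ATGTAACCCAAA", coding = TRUE)
  expect_true(any(grepl("*", vapply(pvg2$nodes, `[[`, character(1), "aa"),
                        fixed = TRUE)))
  # member nodes translate their alternative sequence: GAT>AAT is D>N
  seq <- paste0("ATG", strrep("GCT", 4), "GAT", strrep("ACT", 4), "AAA")
  v <- snv("V1", 15L, "G", "A")
  pvg3 <- translate_graph(seq, coding = TRUE, variants = v)
  aas3 <- vapply(pvg3$nodes, `[[`, character(1), "aa")
  kinds <- vapply(pvg3$nodes, `[[`, character(1), "kind")
  expect_setequal(unname(aas3[kinds == "member"]), c("D", "N"))
  # selenocysteine position inside an anchor
  seq_u <- paste0("ATG", "TGA", strrep("AAA", 5))
  pvg4 <- translate_graph(seq_u, coding = TRUE, sec_positions = 3L)
  expect_true(any(grepl("U", vapply(pvg4$nodes, `[[`, character(1),
                                    "aa"))))
})

test_that("cleavage motifs spanning node boundaries are found", {
  # member path ends ...WK and the next anchor starts with P: the WK/P
  # override cuts between K and P even across the node boundary
  seq <- paste0("ATG", "TGGAAG", "CCT", strrep("GCA", 6), "AAA")
  # ref: M W K P A A A A A A K ; SNV turns W into C in the member path
  v <- snv("V1", 4L, "G", "C") # TGG -> TCG: W -> S
  pvg <- translate_graph(seq, coding = TRUE, variants = v)
  pcg <- to_cleavage_graph(pvg, "trypsin")
  peps <- extend_miscleavages(pcg, call_params(min_length = 1L,
                                               max_length = 30L,
                                               max_miscleavage = 0L))
  # reference path: cut after WK (override); variant path: S kills the
  # override so KP stays uncut
  expect_true("MWK" %in% peps$peptide)
  expect_false("MSK" %in% peps$peptide)
  expect_true(any(grepl("^MSKP", peps$peptide)))
})

test_that("PCG digestion of a plain sequence equals direct digestion", {
  set.seed(23)
  for (i in 1:15) {
    n_aa <- sample(10:60, 1)
    # random coding sequence without internal stops
    tab <- codon_table()
    sense <- names(tab)[!tab %in% "*"]
    seq <- paste(sample(sense, n_aa, replace = TRUE), collapse = "")
    prot <- translate_nt(seq)
    params <- call_params(min_length = 2L, max_length = 20L,
                          max_miscleavage = 2L)
    pvg <- translate_graph(seq, coding = TRUE)
    pcg <- to_cleavage_graph(pvg, params$enzyme)
    got <- sort(unique(extend_miscleavages(pcg, params)$peptide))
    want <- sort(digest_protein(prot, params$enzyme, max_mc = 2L,
                                min_len = 2L, max_len = 20L))
    expect_equal(got, want)
  }
})

test_that("PCG segments contain no internal cleavage sites (idempotence)", {
  set.seed(29)
  seq <- rand_dna(240)
  v <- snv("V1", 60L, substr(seq, 61, 61),
           setdiff(c("A", "C", "G", "T"), substr(seq, 61, 61))[1])
  pvg <- translate_graph(seq, coding = FALSE, variants = v)
  pcg <- to_cleavage_graph(pvg, "trypsin")
  for (s in pcg$segments) {
    if (nchar(s$aa) >= 2L) {
      expect_length(cleavage_sites(s$aa, "trypsin"), 0L)
    }
  }
})

test_that("miscleavage extension enumerates bounded concatenations", {
  # linear AK|BK|CK with generous bounds
  seq <- paste0("ATG", "GCTAAG", "TGTAAG", "GATAAG", "GGG")
  # M A K C K D K G
  params <- call_params(min_length = 1L, max_length = 30L,
                        max_miscleavage = 2L)
  pvg <- translate_graph(seq, coding = TRUE)
  pcg <- to_cleavage_graph(pvg, params$enzyme)
  peps <- extend_miscleavages(pcg, params)
  expect_setequal(
    peps$peptide,
    c("MAK", "MAKCK", "MAKCKDK", "CK", "CKDK", "CKDKG", "DK", "DKG", "G"))
  mc0 <- extend_miscleavages(pcg, params, max_mc = 0L)
  expect_setequal(mc0$peptide, c("MAK", "CK", "DK", "G"))
})
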