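# Shared fixtures: toy genomes/annotations built in code, plus small
# independent oracles used to cross-check the package's primitives.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent residue-by-residue digestion oracle: a plain loop over
# positions applying each protease rule literally (no vectorized reuse of
# the package's site finder).
scan_cut_sites <- function(aa, enzyme_name) {
  r <- strsplit(aa, "", fixed = TRUE)[[1]]
  n <- length(r)
  sites <- integer(0)
  if (n < 2L) return(sites)
  for (i in seq_len(n - 1L)) {
    before <- r[i]
    after <- r[i + 1L]
    before2 <- if (i >= 2L) r[i - 1L] else ""
    cut <- switch(enzyme_name,
      trypsin = {
        hit <- before %in% c("K", "R")
        if (hit && after == "P") {
          before == "K" && before2 == "W"
        } else hit
      },
      lysc = before == "K",
      lysn = after == "K",
      argc = before == "R",
      gluc = before == "E",
      aspn = after == "D",
      chymotrypsin = {
        hit <- before %in% c("F", "W", "Y")
        hit && after != "P"
      },
      stop("unknown enzyme in oracle")
    )
    if (cut) sites <- c(sites, i)
  }
  sites
}

# A two-gene toy genome + GTF used across annotation/parser tests.
toy_reference <- function() {
  chr1 <- paste0(
    "GATTACAGATTACAGATTACAGATTACAGATTACA", # 0-34 padding
    rand_dna(0)
  )
  # deterministic 200-nt chromosome
  set.seed(42)
  chr1 <- rand_dna(200)
  # plus-strand single-exon coding transcript TXP: exon [100,130), CDS
  # [106,127)
  substr(chr1, 107, 109) <- "ATG"
  gtf <- paste(
    c(
      paste("chr1\ttoy\ttranscript\t101\t130\t.\t+\t.",
            'gene_id "G1"; transcript_id "TXP";', sep = "\t"),
      paste("chr1\ttoy\texon\t101\t130\t.\t+\t.",
            'gene_id "G1"; transcript_id "TXP";', sep = "\t"),
      paste("chr1\ttoy\tCDS\t107\t127\t.\t+\t0",
            'gene_id "G1"; transcript_id "TXP";', sep = "\t"),
      # minus-strand two-exon transcript TXM: exons [100,110) and [120,130)
      paste("chr1\ttoy\ttranscript\t101\t130\t.\t-\t.",
            'gene_id "G2"; transcript_id "TXM";', sep = "\t"),
      paste("chr1\ttoy\texon\t101\t110\t.\t-\t.",
            'gene_id "G2"; transcript_id "TXM";', sep = "\t"),
      paste("chr1\ttoy\texon\t121\t130\t.\t-\t.",
            'gene_id "G2"; transcript_id "TXM";', sep = "\t")
    ),
    collapse = "\n"
  )
  list(genome = genome_assembly(chr1 = chr1), gtf = gtf)
}

# Random single-exon transcript model over its own sequence space.
seq_model <- function(seq, cds_start = NA_integer_, sec = integer(0)) {
  L <- nchar(seq)
  transcript_model(
    "TX", "GENE", "chr1", "+", cbind(0L, L),
    cds_start_tx = cds_start,
    cds_end_tx = if (is.na(cds_start)) NA_integer_ else
      cds_start + 3L * ((L - cds_start) %/% 3L),
    selenocysteine_tx = sec
  )
}

snv <- function(id, pos, ref, alt, tx = "TX") {
  variant_table(id, "GENE", tx, pos, pos + 1L, ref, alt, "SNV", "gSNP")
}

random_variant_table <- function(n, max_pos = 500L) {
  pos <- sample.int(max_pos, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                        1L), character(1))
  variant_table(paste0("R", seq_len(n)), sample(c("GA", "GB"), n, TRUE),
                "TX", pos, pos + 1L, ref, alt, "SNV",
                sample(c("gSNP", "sSNV", "RNAEditing"), n, TRUE))
}
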