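# Fuzz testing: simulated transcript models, variant sets and backbones,
# with an independent brute-force oracle that enumerates every compatible
# variant combination by string editing.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.rand_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Default fuzz configuration
#'
#' Sequence lengths 60-600 nt, 1-12 variants per case, 70% SNV / 20%
#' indel / 10% other (RNA editing, retained introns with optional nested
#' variants, exon skips, substitutions), indel lengths 1-9 nt, 60% coding
#' transcripts, occasional selenocysteine.
#'
#' @param seq_len_range,n_variants_range Integer ranges.
#' @param type_weights Named weights for `snv`, `indel`, `other`.
#' @param kind One of `"linear"`, `"fusion"`, `"circ"`.
#' @param coding_prob,sec_prob Transcript property probabilities.
#' @return A list.
#' @export
fuzz_config <- function(seq_len_range = c(60L, 600L),
                        n_variants_range = c(1L, 12L),
                        type_weights = c(snv = 0.7, indel = 0.2,
                                         other = 0.1),
                        kind = "linear", coding_prob = 0.6,
                        sec_prob = 0.1) {
  stopifnot(kind %in% c("linear", "fusion", "circ"))
  list(seq_len_range = as.integer(seq_len_range),
       n_variants_range = as.integer(n_variants_range),
       type_weights = type_weights, kind = kind,
       coding_prob = coding_prob, sec_prob = sec_prob)
}

# Draw variants over positions [lo, L) of a sequence, honoring the
# edge-case placement constraints. Returns a variant_table (coordinates in
# the sequence's own space) with `tx_id` set.
.sim_variants <- function(seq, n, lo, tx_id, type_weights, id_prefix = "V") {
  L <- nchar(seq)
  rows <- list()
  counter <- 0L
  hi <- L - 11L
  if (hi <= lo) return(empty_variant_table())
  for (i in seq_len(n)) {
    counter <- counter + 1L
    kind <- sample(names(type_weights), 1L, prob = type_weights)
    p <- sample(lo:hi, 1L)
    vid <- paste0(id_prefix, counter)
    base <- substr(seq, p + 1L, p + 1L)
    if (kind == "snv") {
      alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
      src <- if (stats::runif(1) < 0.15) "RNAEditing" else
        sample(c("gSNP", "sSNV"), 1L)
      rows[[length(rows) + 1L]] <- variant_table(
        vid, "GENE", tx_id, p, p + 1L, base, alt, "SNV", src)
    } else if (kind == "indel") {
      d <- sample(1:9, 1L)
      if (stats::runif(1) < 0.5) { # insertion, VCF-anchored
        rows[[length(rows) + 1L]] <- variant_table(
          vid, "GENE", tx_id, p, p + 1L, base,
          paste0(base, .rand_nt(d)), "INSERTION",
          sample(c("gIndel", "sIndel"), 1L))
      } else {
        if (p + d + 1L > L - 2L) d <- max(1L, L - 3L - p)
        ref <- substr(seq, p + 1L, p + 1L + d)
        rows[[length(rows) + 1L]] <- variant_table(
          vid, "GENE", tx_id, p, p + d + 1L, ref, base, "DELETION",
          sample(c("gIndel", "sIndel"), 1L))
      }
    } else { # alternative-splicing-like events
      sub <- sample(c("ri", "se", "mxe"), 1L)
      if (sub == "ri") {
        ins <- .rand_nt(sample(6:45, 1L))
        rows[[length(rows) + 1L]] <- variant_table(
          vid, "GENE", tx_id, p, p, "", ins, "ALT_SPLICE_RI", "AltSplice")
        if (stats::runif(1) < 0.5) { # nested small variant inside
          counter <- counter + 1L
          np <- sample(0:(nchar(ins) - 1L), 1L)
          nb <- substr(ins, np + 1L, np + 1L)
          rows[[length(rows) + 1L]] <- variant_table(
            paste0(id_prefix, counter), "GENE", tx_id, np, np + 1L, nb,
            sample(setdiff(c("A", "C", "G", "T"), nb), 1L), "SNV",
            "sSNV", parent_id = vid)
        }
      } else if (sub == "se") {
        d <- min(sample(9:60, 1L), L - 3L - p)
        if (d < 3L) next
        rows[[length(rows) + 1L]] <- variant_table(
          vid, "GENE", tx_id, p, p + d, substr(seq, p + 1L, p + d), "",
          "ALT_SPLICE_SE", "AltSplice")
      } else {
        d <- min(sample(6:30, 1L), L - 3L - p)
        if (d < 3L) next
        rows[[length(rows) + 1L]] <- variant_table(
          vid, "GENE", tx_id, p, p + d, substr(seq, p + 1L, p + d),
          .rand_nt(sample(6:30, 1L)), "ALT_SPLICE_MXE", "AltSplice")
      }
    }
  }
  if (!length(rows)) return(empty_variant_table())
  do.call(rbind, rows)
}

#' Simulate a fuzz case
#'
#' Draws a transcript model (coding status, ORF position, selenocysteine,
#' strand), an artificial sequence and a variant set per the
#' configuration. Deterministic per seed: repeated invocation yields an
#' identical case.
#'
#' @param seed Integer seed.
#' @param config A [fuzz_config()].
#' @return A list of class `fuzz_case`.
#' @export
simulate_case <- function(seed, config = fuzz_config()) {
  .with_seed(seed, {
    L <- sample(config$seq_len_range[1]:config$seq_len_range[2], 1L)
    n_var <- sample(config$n_variants_range[1]:config$n_variants_range[2],
                    1L)
    if (n_var > L %/% 4L) {
      stop("infeasible fuzz config: ", n_var, " variants over ", L, " nt")
    }
    strand <- sample(c("+", "-"), 1L)
    kind <- config$kind
    if (kind == "linear") {
      seq <- .rand_nt(L)
      coding <- stats::runif(1) < config$coding_prob
      cds_start <- NA_integer_
      sec <- integer(0)
      if (coding) {
        cds_start <- sample(0:max(0L, min(24L, L - 45L)), 1L)
        substr(seq, cds_start + 1L, cds_start + 3L) <- "ATG"
        if (stats::runif(1) < config$sec_prob) {
          slot <- cds_start + 3L * sample(2:8, 1L)
          if (slot + 3L <= L) {
            substr(seq, slot + 1L, slot + 3L) <- "TGA"
            sec <- slot
          }
        }
      }
      lo <- if (coding) cds_start + 3L else 0L
      variants <- .sim_variants(seq, n_var, lo, "TX1", config$type_weights)
      model <- transcript_model(
        "TX1", "GENE", "chr1", strand,
        exons = cbind(0L, L), # sequence-space model; exon structure is
        cds_start_tx = cds_start, # exercised by the annotation tests
        cds_end_tx = if (coding) cds_start + 3L * ((L - cds_start) %/% 3L)
        else NA_integer_,
        selenocysteine_tx = sec
      )
      structure(list(seed = seed, kind = kind, seq = seq, model = model,
                     coding = coding, orf0 = if (coding) cds_start else 0L,
                     sec = sec, variants = variants,
                     canonical = .case_canonical(seq, coding, cds_start,
                                                 sec)),
                class = "fuzz_case")
    } else if (kind == "fusion") {
      Ld <- max(90L, L)
      La <- sample(60:300, 1L)
      donor <- .rand_nt(Ld)
      acceptor <- .rand_nt(La)
      coding <- stats::runif(1) < config$coding_prob
      cds_start <- NA_integer_
      if (coding) {
        cds_start <- sample(0:12, 1L)
        substr(donor, cds_start + 1L, cds_start + 3L) <- "ATG"
      }
      bp_d <- sample((if (coding) cds_start + 9L else 15L):(Ld - 15L), 1L)
      bp_a <- sample(3:(La - 30L), 1L)
      nd <- max(1L, n_var %/% 2L)
      na_ <- n_var - nd
      vd <- .sim_variants(substr(donor, 1L, bp_d + 1L), nd,
                          if (coding) cds_start + 3L else 0L,
                          "TXD", config$type_weights, id_prefix = "VD")
      va <- .sim_variants(acceptor, na_, bp_a + 1L, "TXA",
                          config$type_weights, id_prefix = "VA")
      structure(list(seed = seed, kind = kind,
                     donor_seq = donor, acceptor_seq = acceptor,
                     coding = coding,
                     cds_start = cds_start,
                     bp_d = bp_d, bp_a = bp_a,
                     donor_variants = vd, acceptor_variants = va,
                     canonical = .case_canonical(donor, coding, cds_start,
                                                 integer(0))),
                class = "fuzz_case")
    } else { # circ
      seq <- .rand_nt(max(L, 120L))
      s <- sample(3:30, 1L)
      circ_len <- sample(9:60, 1L)
      e <- s + circ_len
      nv <- min(n_var, 3L)
      circ_seq_ref <- substr(seq, s + 1L, e)
      cv <- .sim_variants(circ_seq_ref, nv, 0L, "TX1",
                          c(snv = 0.8, indel = 0.2), id_prefix = "VC")
      # shift into transcript coordinates
      if (nrow(cv)) {
        top <- is.na(cv$parent_id)
        cv$start[top] <- cv$start[top] + s
        cv$end[top] <- cv$end[top] + s
      }
      structure(list(seed = seed, kind = kind, seq = seq,
                     circ_span = c(s, e), variants = cv,
                     coding = FALSE, canonical = character(0)),
                class = "fuzz_case")
    }
  })
}

.case_canonical <- function(seq, coding, cds_start, sec) {
  if (!coding) return(character(0))
  p <- translate_nt(substr(seq, cds_start + 1L, nchar(seq)),
                    sec_positions = sec - cds_start)
  stats::setNames(p, "CANON1")
}

# ---- brute-force oracle ------------------------------------------------

# Valid subsets as index vectors: every nested record's parent present;
# all pairs compatible. Enumerated by bitmask (error beyond
# `max_variants`).
.oracle_subsets <- function(variants, max_variants = 20L) {
  n <- nrow(variants)
  if (n == 0L) return(list(integer(0)))
  if (n > max_variants) {
    stop("brute force: ", n, " variants exceed the enumeration cap (",
         max_variants, "); shrink the case")
  }
  comp <- variant_compatibility(variants)
  vid <- variants$variant_id
  pid <- variants$parent_id
  bits <- 2L^(seq_len(n) - 1L)
  out <- vector("list", 2L^n)
  cnt <- 0L
  for (mask in 0:(2L^n - 1L)) {
    idx <- which(bitwAnd(mask, bits) > 0L)
    ok <- TRUE
    for (i in idx) {
      if (!is.na(pid[i]) && !pid[i] %in% vid[idx]) {
        ok <- FALSE
        break
      }
    }
    if (ok && length(idx) > 1L && !all(comp[idx, idx])) ok <- FALSE
    if (ok) {
      cnt <- cnt + 1L
      out[[cnt]] <- idx
    }
  }
  out[seq_len(cnt)]
}

# Lean subset application used by the oracle: `cols` holds the variant
# table's columns as plain vectors; `idx` selects the subset.
.oracle_edit <- function(seq, idx, cols, positions = integer(0)) {
  if (!length(idx)) return(list(seq = seq, positions = positions))
  top <- idx[is.na(cols$pid[idx])]
  alt_r <- character(length(top))
  for (t in seq_along(top)) {
    i <- top[t]
    nst <- idx[!is.na(cols$pid[idx]) & cols$pid[idx] == cols$vid[i]]
    a <- cols$alt[i]
    if (length(nst)) {
      for (j in nst[order(cols$start[nst], decreasing = TRUE)]) {
        a <- paste0(substr(a, 1L, cols$start[j]), cols$alt[j],
                    substr(a, cols$end[j] + 1L, nchar(a)))
      }
    }
    alt_r[t] <- a
  }
  s <- cols$start[top]
  e <- cols$end[top]
  ord <- order(s, e, decreasing = TRUE)
  out <- seq
  for (t in ord) {
    out <- paste0(substr(out, 1L, s[t]), alt_r[t],
                  substr(out, e[t] + 1L, nchar(out)))
  }
  if (length(positions)) {
    keep <- !vapply(positions, function(p) any(s <= p & e > p), logical(1))
    shifted <- vapply(positions, function(p) {
      b <- e <= p
      as.integer(p + sum(nchar(alt_r[b]) - (e[b] - s[b])))
    }, integer(1))
    positions <- shifted[keep]
  }
  list(seq = out, positions = positions)
}

# Digest an ORF window of a translated frame string. `sites` are 1-based
# cut-after-residue positions for the whole string; the window is residues
# from..to (1-based, inclusive); `end_is_boundary` marks whether `to` is a
# real peptide end (stop codon or physical sequence end) as opposed to an
# artificial window cap.
.oracle_window_peptides <- function(aa, from, to, sites, max_mc, min_len,
                                    max_len, end_is_boundary = TRUE) {
  if (to < from) return(character(0))
  starts_at <- sites[sites >= from & sites < to]
  bounds <- c(from - 1L, starts_at)
  ends <- sites[sites >= from & sites <= to] # a cut at the window end is
  if (end_is_boundary) ends <- c(ends, to)   # a genuine peptide end
  ends <- sort(unique(ends))
  out <- character(0)
  for (bi in seq_along(bounds)) {
    b <- bounds[bi]
    es <- ends[ends > b]
    mc <- 0L
    for (e in es) {
      len <- e - b
      if (len > max_len) break
      if (mc > max_mc) break
      if (len >= min_len) out <- c(out, substr(aa, b + 1L, e))
      mc <- mc + 1L
    }
  }
  out
}

#' Brute-force enumeration of expected non-canonical peptides
#'
#' Iterates over every compatible variant subset, applies it to the
#' backbone by string editing, translates (the known ORF for coding
#' backbones, all methionine starts in three frames for noncoding and
#' circular ones, rolling through the back-splice junction up to three
#' traversals for circles), digests, applies length/miscleavage bounds and
#' canonical exclusion, and unions the results. Independent of the graph
#' pipeline.
#'
#' @param case A [simulate_case()] result.
#' @param params A [call_params()].
#' @return Sorted character vector of expected peptides.
#' @export
brute_force_peptides <- function(case, params = call_params()) {
  enzyme <- params$enzyme
  mc <- params$max_miscleavage
  mn <- params$min_length
  mx <- params$max_length
  canonical <- canonical_digest_set(case$canonical, params)
  acc <- vector("list", 256L)
  n_acc <- 0L
  keep <- function(x) {
    if (length(x)) {
      n_acc <<- n_acc + 1L
      acc[[n_acc]] <<- x
    }
  }
  cols_of <- function(df) {
    list(vid = df$variant_id, pid = df$parent_id, tx = df$tx_id,
         start = df$start, end = df$end, ref = df$ref, alt = df$alt)
  }

  frame_orf_peptides <- function(seq, sec = integer(0)) {
    # all-M three-frame novel-ORF peptides of a linear string
    res <- character(0)
    for (k in 0:2) {
      aa <- translate_nt(substr(seq, k + 1L, nchar(seq)),
                         sec_positions = sec - k,
                         stop_behavior = "keep_stops")
      if (!nchar(aa)) next
      sites <- cleavage_sites(aa, enzyme)
      r <- strsplit(aa, "", fixed = TRUE)[[1]]
      stops <- which(r == "*")
      for (j in which(r == "M")) {
        nxt <- stops[stops > j]
        to <- if (length(nxt)) nxt[1] - 1L else length(r)
        res <- c(res, .oracle_window_peptides(aa, j, to, sites, mc, mn, mx))
      }
    }
    res
  }

  if (case$kind == "linear") {
    cols <- cols_of(case$variants)
    for (idx in .oracle_subsets(case$variants)) {
      ed <- .oracle_edit(case$seq, idx, cols, positions = case$sec)
      if (case$coding) {
        o <- case$orf0
        aa <- translate_nt(substr(ed$seq, o + 1L, nchar(ed$seq)),
                           sec_positions = ed$positions - o,
                           stop_behavior = "keep_stops")
        stop_at <- regexpr("*", aa, fixed = TRUE)
        to <- if (stop_at > 0L) stop_at - 1L else nchar(aa)
        keep(.oracle_window_peptides(aa, 1L, to,
                                     cleavage_sites(aa, enzyme),
                                     mc, mn, mx))
      } else {
        keep(frame_orf_peptides(ed$seq, ed$positions))
      }
    }
  } else if (case$kind == "fusion") {
    donor_keep <- case$bp_d + 1L
    all_v <- rbind(case$donor_variants, case$acceptor_variants)
    cols <- cols_of(all_v)
    cols_a <- cols
    cols_a$start <- cols_a$start -
      ifelse(cols$tx == "TXA" & is.na(cols$pid), case$bp_a, 0L)
    cols_a$end <- cols_a$end -
      ifelse(cols$tx == "TXA" & is.na(cols$pid), case$bp_a, 0L)
    donor_stub <- substr(case$donor_seq, 1L, donor_keep)
    acc_stub <- substr(case$acceptor_seq, case$bp_a + 1L,
                       nchar(case$acceptor_seq))
    for (idx in .oracle_subsets(all_v)) {
      d_idx <- idx[cols$tx[idx] == "TXD"]
      a_idx <- idx[cols$tx[idx] == "TXA"]
      fused <- paste0(.oracle_edit(donor_stub, d_idx, cols)$seq,
                      .oracle_edit(acc_stub, a_idx, cols_a)$seq)
      if (case$coding) {
        o <- case$cds_start
        aa <- translate_nt(substr(fused, o + 1L, nchar(fused)),
                           stop_behavior = "keep_stops")
        stop_at <- regexpr("*", aa, fixed = TRUE)
        to <- if (stop_at > 0L) stop_at - 1L else nchar(aa)
        keep(.oracle_window_peptides(aa, 1L, to,
                                     cleavage_sites(aa, enzyme),
                                     mc, mn, mx))
      } else {
        keep(frame_orf_peptides(fused))
      }
    }
  } else { # circ: rolling windows of three traversals per rotation
    s0 <- case$circ_span[1]
    circ_ref <- substr(case$seq, s0 + 1L, case$circ_span[2])
    cv <- case$variants
    if (nrow(cv)) {
      top <- is.na(cv$parent_id)
      cv$start[top] <- cv$start[top] - s0
      cv$end[top] <- cv$end[top] - s0
    }
    cols <- cols_of(cv)
    for (idx in .oracle_subsets(cv)) {
      circ2 <- .oracle_edit(circ_ref, idx, cols)$seq
      L2 <- nchar(circ2)
      full <- strrep(circ2, 4L)
      for (k in 0:2) {
        aa <- translate_nt(substr(full, k + 1L, nchar(full)),
                           stop_behavior = "keep_stops")
        if (!nchar(aa)) next
        sites <- cleavage_sites(aa, enzyme)
        r <- strsplit(aa, "", fixed = TRUE)[[1]]
        stops <- which(r == "*")
        for (j in which(r == "M")) {
          if (k + 3L * (j - 1L) >= L2) next # starts in first traversal
          nxt <- stops[stops > j]
          cap <- j - 1L + L2 # three traversals = L2 codons
          if (length(nxt) && nxt[1] - 1L <= cap) {
            keep(.oracle_window_peptides(aa, j, nxt[1] - 1L, sites,
                                         mc, mn, mx,
                                         end_is_boundary = TRUE))
          } else {
            keep(.oracle_window_peptides(aa, j, min(cap, length(r)),
                                         sites, mc, mn, mx,
                                         end_is_boundary = FALSE))
          }
        }
      }
    }
  }
  peps <- unique(unlist(acc[seq_len(n_acc)], use.names = FALSE))
  if (is.null(peps)) peps <- character(0)
  peps <- peps[!grepl("X", peps, fixed = TRUE)]
  sort(setdiff(peps, canonical))
}

#' Run the graph pipeline on a fuzz case
#'
#' @param case A [simulate_case()] result.
#' @param params A [call_params()].
#' @return Sorted character vector of called peptides.
#' @export
call_case_peptides <- function(case, params = call_params()) {
  canonical <- canonical_digest_set(case$canonical, params)
  if (case$kind == "linear") {
    ent <- call_variant_peptides(case$seq, case$model, case$variants,
                                 params, canonical_digest = canonical,
                                 apply_edge_rules = FALSE)
  } else if (case$kind == "fusion") {
    genome <- genome_assembly(chrD = case$donor_seq,
                              chrA = case$acceptor_seq)
    annotation <- list(
      TXD = transcript_model(
        "TXD", "GENED", "chrD", "+",
        exons = cbind(0L, nchar(case$donor_seq)),
        cds_start_tx = if (case$coding) case$cds_start else NA_integer_,
        cds_end_tx = if (case$coding) {
          case$cds_start +
            3L * ((nchar(case$donor_seq) - case$cds_start) %/% 3L)
        } else NA_integer_
      ),
      TXA = transcript_model("TXA", "GENEA", "chrA", "+",
                             exons = cbind(0L, nchar(case$acceptor_seq)))
    )
    ev <- fusion_event("TXD", "TXA", "GENED", "GENEA",
                       donor_bp_tx = case$bp_d,
                       acceptor_bp_tx = case$bp_a)
    bb <- build_fusion_backbone(ev, annotation, genome,
                                rbind(case$donor_variants,
                                      case$acceptor_variants))
    ent <- call_fusion_peptides(bb, params, canonical_digest = canonical)
  } else {
    cm <- circ_rna_model("CIRC1", "TX1", "GENE",
                         segments = rbind(case$circ_span))
    bb <- build_circ_backbone(cm, case$seq, case$variants)
    ent <- call_circ_peptides(bb, params, canonical_digest = canonical)
  }
  sort(unique(ent$peptide))
}

#' Compare expected and called peptide sets
#'
#' @param expected,got Character vectors of peptides.
#' @return List with `pass`, `missing` (expected but not called) and
#'   `extra` (called but not expected).
#' @export
compare_peptide_sets <- function(expected, got) {
  missing <- setdiff(expected, got)
  extra <- setdiff(got, expected)
  list(pass = !length(missing) && !length(extra),
       missing = missing, extra = extra)
}

#' Fuzz the graph pipeline against the brute-force oracle
#'
#' @param n Number of cases.
#' @param seed Base seed; case `i` uses `seed * 1000 + i` (kept within
#'   32-bit range).
#' @param config A [fuzz_config()].
#' @param params A [call_params()].
#' @return List with `summary` (data.frame: seed, kind, n_variants, pass)
#'   and `failures` (named list of diff reports, empty on full agreement).
#' @export
fuzz_run <- function(n = 100L, seed = 1L, config = fuzz_config(),
                     params = call_params()) {
  rows <- list()
  failures <- list()
  for (i in seq_len(n)) {
    case_seed <- (seed * 1009L + i * 7L) %% 2147483647L
    case <- simulate_case(case_seed, config)
    expected <- brute_force_peptides(case, params)
    got <- call_case_peptides(case, params)
    cmp <- compare_peptide_sets(expected, got)
    rows[[i]] <- data.frame(
      seed = case_seed, kind = case$kind,
      n_variants = if (!is.null(case$variants)) nrow(case$variants)
      else nrow(case$donor_variants) + nrow(case$acceptor_variants),
      n_expected = length(expected), pass = cmp$pass,
      stringsAsFactors = FALSE
    )
    if (!cmp$pass) failures[[as.character(case_seed)]] <- cmp
  }
  list(summary = do.call(rbind, rows), failures = failures)
}
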