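# Parsers converting upstream caller outputs into gene-centric variant
# records (GVF) and event models. Small variants arrive VEP-annotated with
# genomic coordinates and affected transcript IDs; fusion, alternative
# splicing, RNA editing and circRNA tables are consumed in their native
# (tab-separated) shapes.

# Genomic footprint touching the 2 intronic nt flanking any exon boundary.
.touches_splice_flank <- function(tx, g0, g1) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(FALSE)
  for (i in seq_len(nrow(ex))) {
    if (i > 1L) { # acceptor-side flank (2 nt before exon start)
      fs <- ex[i, "start"] - 2L
      if (g0 < ex[i, "start"] && g1 > fs) return(TRUE)
    }
    if (i < nrow(ex)) { # donor-side flank (2 nt after exon end)
      fe <- ex[i, "end"] + 2L
      if (g0 < fe && g1 > ex[i, "end"]) return(TRUE)
    }
  }
  FALSE
}

.parse_small_variant_rows <- function(rows, annotation, genome,
                                      source_snv, source_indel,
                                      type_snv = "SNV") {
  out <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    tx <- annotation[[r$transcript_id]]
    if (is.null(tx)) {
      warning("variant at ", r$chrom, ":", r$pos, ": unknown transcript '",
              r$transcript_id, "'; skipped")
      next
    }
    ref <- toupper(r$ref)
    alt <- toupper(r$alt)
    g0 <- r$pos - 1L
    g1 <- g0 + nchar(ref)
    seen <- genome_subseq(genome, r$chrom, g0, g1)
    if (!identical(seen, ref)) {
      warning("variant at ", r$chrom, ":", r$pos, ": ref allele '", ref,
              "' does not match genome '", seen, "'; rejected")
      next
    }
    if (.touches_splice_flank(tx, g0, g1)) next # splice-site-altering
    tx_pos <- genomic_to_tx(tx, g0:(max(g0, g1 - 1L)))
    if (anyNA(tx_pos)) next # not (fully) exonic for this transcript
    if (tx$strand == "+") {
      start_tx <- tx_pos[1]
      ref_tx <- ref
      alt_tx <- alt
    } else {
      start_tx <- tx_pos[length(tx_pos)]
      ref_tx <- reverse_complement(ref)
      alt_tx <- reverse_complement(alt)
    }
    s_ref <- nchar(ref)
    s_alt <- nchar(alt)
    type <- if (s_ref == 1L && s_alt == 1L) type_snv
    else if (s_ref < s_alt) "INSERTION"
    else if (s_ref > s_alt) "DELETION"
    else "SUBSTITUTION"
    src <- if (s_ref == 1L && s_alt == 1L) source_snv else source_indel
    out[[length(out) + 1L]] <- variant_table(
      variant_id = paste0(r$chrom, ":", r$pos, ":", ref, ">", alt),
      gene_id = tx$gene_id, tx_id = tx$transcript_id,
      start = start_tx, end = start_tx + s_ref,
      ref = ref_tx, alt = alt_tx, type = type, source = src,
      consequence = if ("consequence" %in% names(r)) r$consequence else
        NA_character_
    )
  }
  if (!length(out)) return(empty_variant_table())
  do.call(rbind, out)
}

#' Parse VEP-annotated small variants into gene-centric records
#'
#' One record per affected transcript, with genomic coordinates resolved
#' into transcript space; records on `-` strand transcripts have ref/alt
#' reverse-complemented. Records whose reference allele mismatches the
#' genome are rejected with a diagnostic; records on unknown transcripts
#' are skipped with a warning; records not fully within an exon of the
#' transcript — or touching the 2 intronic nt flanking an exon — are
#' dropped. Indels follow the VCF anchor-base convention (the anchored
#' span is kept as-is).
#'
#' @param vep_records data.frame with columns `chrom`, `pos` (1-based
#'   genomic), `ref`, `alt`, `transcript_id`, optionally `consequence`.
#' @param annotation Named list of [transcript_model()].
#' @param genome A `genome_assembly`.
#' @param somatic Use somatic source tags (`sSNV`/`sIndel`) instead of
#'   germline (`gSNP`/`gIndel`).
#' @return A `variant_table`.
#' @export
parse_vep <- function(vep_records, annotation, genome, somatic = FALSE) {
  .parse_small_variant_rows(
    vep_records, annotation, genome,
    source_snv = if (somatic) "sSNV" else "gSNP",
    source_indel = if (somatic) "sIndel" else "gIndel"
  )
}

#' Parse RNA-editing sites into gene-centric records
#'
#' Single-base substitutions (e.g. A-to-I reported as A>G) handled as in
#' [parse_vep()], restricted to SNVs, with source tag `RNAEditing`.
#' Intronic sites are dropped; reference mismatches rejected.
#'
#' @param rows data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `transcript_id`.
#' @inheritParams parse_vep
#' @return A `variant_table`.
#' @export
parse_rna_editing <- function(rows, annotation, genome) {
  bad <- nchar(rows$ref) != 1L | nchar(rows$alt) != 1L
  if (any(bad)) {
    warning(sum(bad), " non-single-base editing site(s) dropped")
    rows <- rows[!bad, , drop = FALSE]
  }
  .parse_small_variant_rows(rows, annotation, genome,
                            source_snv = "RNAEditing",
                            source_indel = "RNAEditing")
}

#' Parse fusion calls into per-transcript-pair events
#'
#' Fusion callers report gene-level events; the most comprehensive
#' interpretation is that a fusion may involve any transcript of the donor
#' and acceptor genes, so one [fusion_event()] is produced per (donor
#' transcript x acceptor transcript) pair. Breakpoints are classified
#' exonic or intronic per transcript. Rows whose genes are absent from the
#' annotation are dropped with a warning.
#'
#' @param fusion_rows data.frame with columns `donor_gene`,
#'   `acceptor_gene`, `donor_chrom`, `donor_pos` (1-based genomic position
#'   of the last donor base), `acceptor_chrom`, `acceptor_pos` (first
#'   acceptor base).
#' @param annotation Named list of [transcript_model()].
#' @return List of [fusion_event()].
#' @export
parse_fusion <- function(fusion_rows, annotation) {
  genes <- vapply(annotation, `[[`, character(1), "gene_id")
  out <- list()
  for (i in seq_len(nrow(fusion_rows))) {
    r <- fusion_rows[i, ]
    donors <- annotation[genes == r$donor_gene]
    acceptors <- annotation[genes == r$acceptor_gene]
    if (!length(donors) || !length(acceptors)) {
      warning("fusion row ", i, ": gene '",
              if (!length(donors)) r$donor_gene else r$acceptor_gene,
              "' absent from annotation; dropped")
      next
    }
    for (d in donors) {
      for (a in acceptors) {
        dg <- r$donor_pos - 1L
        ag <- r$acceptor_pos - 1L
        in_body_d <- dg >= d$exons[1, "start"] &&
          dg < d$exons[nrow(d$exons), "end"]
        in_body_a <- ag >= a$exons[1, "start"] &&
          ag < a$exons[nrow(a$exons), "end"]
        if (!in_body_d || !in_body_a) next
        d_tx <- genomic_to_tx(d, dg)
        a_tx <- genomic_to_tx(a, ag)
        out[[length(out) + 1L]] <- fusion_event(
          donor_tx = d$transcript_id, acceptor_tx = a$transcript_id,
          donor_gene = r$donor_gene, acceptor_gene = r$acceptor_gene,
          donor_bp_tx = d_tx, acceptor_bp_tx = a_tx,
          donor_bp_genomic = dg, acceptor_bp_genomic = ag,
          donor_bp_in_intron = is.na(d_tx),
          acceptor_bp_in_intron = is.na(a_tx),
          fusion_id = paste0("FUS:", r$donor_gene, "-", r$acceptor_gene,
                             ":", d$transcript_id, ":", a$transcript_id)
        )
      }
    }
  }
  out
}

#' Parse alternative-splicing events into gene-centric records
#'
#' Each event is re-expressed against every compatible transcript as a
#' deletion (exon skipping), insertion (retained intron, alternative
#' 3'/5' splice-site extension) or substitution (mutually exclusive
#' exons), with the alternative sequence drawn from the genome. Events not
#' reconcilable with any transcript of the gene are dropped with a
#' warning.
#'
#' @param event_rows data.frame with columns `event_type`
#'   (`SE`/`RI`/`A3SS`/`A5SS`/`MXE`), `gene_id`, `chrom`, `exon_start`,
#'   `exon_end` and (for A3SS/A5SS/MXE) `alt_start`, `alt_end` — all
#'   genomic, 0-based half-open.
#' @param annotation Named list of [transcript_model()].
#' @param genome A `genome_assembly`.
#' @return A `variant_table` (types `ALT_SPLICE_*`, source `AltSplice`).
#' @export
parse_alt_splicing <- function(event_rows, annotation, genome) {
  genes <- vapply(annotation, `[[`, character(1), "gene_id")
  out <- list()
  for (i in seq_len(nrow(event_rows))) {
    r <- event_rows[i, ]
    txs <- annotation[genes == r$gene_id]
    matched <- FALSE
    for (tx in txs) {
      rec <- .alt_splice_record(r, tx, genome)
      if (!is.null(rec)) {
        out[[length(out) + 1L]] <- rec
        matched <- TRUE
      }
    }
    if (!matched) {
      warning("alternative-splicing row ", i, " (", r$event_type,
              ") not reconcilable with any transcript of ", r$gene_id,
              "; dropped")
    }
  }
  if (!length(out)) return(empty_variant_table())
  do.call(rbind, out)
}

.alt_splice_record <- function(r, tx, genome) {
  ex <- tx$exons
  has_exon <- function(s, e) any(ex[, 1] == s & ex[, 2] == e)
  gseq <- function(a, b) {
    s <- genome_subseq(genome, tx$chrom, a, b)
    if (tx$strand == "-") reverse_complement(s) else s
  }
  vid <- paste0("AS:", r$event_type, ":", tx$chrom, ":", r$exon_start, "-",
                r$exon_end, ":", tx$transcript_id)
  mk <- function(start, end, ref, alt, type) {
    variant_table(vid, tx$gene_id, tx$transcript_id, start, end, ref, alt,
                  type, "AltSplice")
  }
  if (r$event_type == "SE") {
    if (!has_exon(r$exon_start, r$exon_end)) return(NULL)
    tpos <- genomic_to_tx(tx, c(r$exon_start, r$exon_end - 1L))
    t0 <- min(tpos)
    t1 <- max(tpos) + 1L
    tx_seq <- transcript_sequence(genome, tx)
    return(mk(t0, t1, substr(tx_seq, t0 + 1L, t1), "", "ALT_SPLICE_SE"))
  }
  if (r$event_type == "RI") {
    k <- which(ex[, "end"] == r$exon_start)
    if (!length(k) || k == nrow(ex) ||
        ex[k + 1L, "start"] != r$exon_end) {
      return(NULL)
    }
    ins <- gseq(r$exon_start, r$exon_end)
    t <- if (tx$strand == "+") {
      genomic_to_tx(tx, r$exon_start - 1L) + 1L
    } else {
      genomic_to_tx(tx, r$exon_end) + 1L
    }
    return(mk(t, t, "", ins, "ALT_SPLICE_RI"))
  }
  if (r$event_type %in% c("A3SS", "A5SS")) {
    if (!has_exon(r$exon_start, r$exon_end)) return(NULL)
    if (r$alt_start == r$exon_start && r$alt_end > r$exon_end) {
      a <- r$exon_end
      b <- r$alt_end
      t <- if (tx$strand == "+") genomic_to_tx(tx, a - 1L) + 1L
      else genomic_to_tx(tx, a - 1L) # before the exon's last tx base? no:
      # genomic-right extension: '+' -> after exon end; '-' -> before exon
      # start in transcript space
      if (tx$strand == "-") t <- genomic_to_tx(tx, r$exon_end - 1L)
    } else if (r$alt_end == r$exon_end && r$alt_start < r$exon_start) {
      a <- r$alt_start
      b <- r$exon_start
      t <- if (tx$strand == "+") genomic_to_tx(tx, r$exon_start)
      else genomic_to_tx(tx, r$exon_start) + 1L
    } else {
      return(NULL)
    }
    return(mk(t, t, "", gseq(a, b),
              paste0("ALT_SPLICE_", r$event_type)))
  }
  if (r$event_type == "MXE") {
    if (!has_exon(r$exon_start, r$exon_end)) return(NULL)
    tpos <- genomic_to_tx(tx, c(r$exon_start, r$exon_end - 1L))
    t0 <- min(tpos)
    t1 <- max(tpos) + 1L
    tx_seq <- transcript_sequence(genome, tx)
    return(mk(t0, t1, substr(tx_seq, t0 + 1L, t1),
              gseq(r$alt_start, r$alt_end), "ALT_SPLICE_MXE"))
  }
  NULL
}

#' Parse circRNA calls into circle models
#'
#' For every transcript of the host gene whose exons intersect the
#' back-splice span, the intersected exon pieces (in transcript order)
#' become the circle's segments.
#'
#' @param rows data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open genomic back-splice span).
#' @param annotation Named list of [transcript_model()].
#' @return List of [circ_rna_model()].
#' @export
parse_circ_rna <- function(rows, annotation) {
  genes <- vapply(annotation, `[[`, character(1), "gene_id")
  out <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    for (tx in annotation[genes == r$gene_id]) {
      if (tx$chrom != r$chrom) next
      ex <- tx$exons
      pieces <- list()
      for (j in seq_len(nrow(ex))) {
        a <- max(ex[j, 1], r$start)
        b <- min(ex[j, 2], r$end)
        if (b > a) {
          tpos <- genomic_to_tx(tx, c(a, b - 1L))
          pieces[[length(pieces) + 1L]] <- c(min(tpos), max(tpos) + 1L)
        }
      }
      if (!length(pieces)) next
      segs <- do.call(rbind, pieces)
      segs <- segs[order(segs[, 1]), , drop = FALSE]
      out[[length(out) + 1L]] <- circ_rna_model(
        circ_id = paste0("CIRC:", r$chrom, ":", r$start, "-", r$end, ":",
                         tx$transcript_id),
        tx_id = tx$transcript_id, gene_id = tx$gene_id, segments = segs
      )
    }
  }
  out
}
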