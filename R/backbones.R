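# Non-canonical transcript backbones: fusion transcripts and circular
# RNAs. Both are realized as novel backbones over which the standard
# graph pipeline runs.

#' Construct a fusion event record
#'
#' @param donor_tx,acceptor_tx Transcript IDs.
#' @param donor_gene,acceptor_gene Gene IDs.
#' @param donor_bp_tx Transcript coordinate (0-based) of the last donor
#'   base retained, or `NA` for intronic breakpoints.
#' @param acceptor_bp_tx Transcript coordinate of the first acceptor base
#'   retained, or `NA` for intronic breakpoints.
#' @param donor_bp_genomic,acceptor_bp_genomic 0-based genomic positions
#'   (required for intronic breakpoints).
#' @param donor_bp_in_intron,acceptor_bp_in_intron Intronic breakpoint
#'   flags.
#' @param fusion_id Stable identifier.
#' @return A list of class `fusion_event`.
#' @export
fusion_event <- function(donor_tx, acceptor_tx, donor_gene = NA_character_,
                         acceptor_gene = NA_character_,
                         donor_bp_tx = NA_integer_,
                         acceptor_bp_tx = NA_integer_,
                         donor_bp_genomic = NA_integer_,
                         acceptor_bp_genomic = NA_integer_,
                         donor_bp_in_intron = FALSE,
                         acceptor_bp_in_intron = FALSE,
                         fusion_id = NULL) {
  if (is.null(fusion_id)) {
    fusion_id <- paste0("FUS_", donor_tx, "_", acceptor_tx)
  }
  structure(list(
    donor_tx = donor_tx, acceptor_tx = acceptor_tx,
    donor_gene = donor_gene, acceptor_gene = acceptor_gene,
    donor_bp_tx = donor_bp_tx, acceptor_bp_tx = acceptor_bp_tx,
    donor_bp_genomic = donor_bp_genomic,
    acceptor_bp_genomic = acceptor_bp_genomic,
    donor_bp_in_intron = isTRUE(donor_bp_in_intron),
    acceptor_bp_in_intron = isTRUE(acceptor_bp_in_intron),
    fusion_id = fusion_id
  ), class = "fusion_event")
}

# Intron of `tx` containing genomic position g, as a 0-based half-open
# genomic interval, or NULL.
.intron_containing <- function(tx, g) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(NULL)
  for (i in seq_len(nrow(ex) - 1L)) {
    if (g >= ex[i, "end"] && g < ex[i + 1L, "start"]) {
      return(c(ex[i, "end"], ex[i + 1L, "start"]))
    }
  }
  NULL
}

#' Build a fusion transcript backbone
#'
#' Joins the donor transcript sequence up to the breakpoint with the
#' acceptor sequence from its breakpoint onward. Intronic breakpoints
#' retain the unspliced intronic sequence leading up to (donor) or
#' following (acceptor) the breakpoint, and intronic variants falling in
#' the retained span are included. Donor small variants 5' of the
#' breakpoint and acceptor variants 3' of it are mapped into backbone
#' coordinates; variants overlapping a breakpoint are dropped with a
#' warning. The donor ORF start is used when the donor is coding and its
#' start codon lies in the retained segment; otherwise the backbone is
#' treated as noncoding.
#'
#' @param event A [fusion_event()].
#' @param annotation Named list of [transcript_model()] (by transcript id).
#' @param genome A `genome_assembly`.
#' @param variants `variant_table` in transcript coordinates (donor and
#'   acceptor records identified via `tx_id`).
#' @param genomic_variants Optional data.frame (`pos` 0-based genomic,
#'   `ref`, `alt`, `variant_id`, `chrom`) of intronic variants to map into
#'   retained introns.
#' @return A list of class `fusion_backbone`: `seq`, `model`
#'   (a [transcript_model()]-like stub), `variants` (backbone
#'   coordinates), `donor_len`, `fusion_id`.
#' @export
build_fusion_backbone <- function(event, annotation, genome,
                                  variants = empty_variant_table(),
                                  genomic_variants = NULL) {
  donor <- annotation[[event$donor_tx]]
  acceptor <- annotation[[event$acceptor_tx]]
  if (is.null(donor) || is.null(acceptor)) {
    stop("fusion ", event$fusion_id, ": transcript absent from annotation")
  }
  donor_seq_full <- transcript_sequence(genome, donor)
  acceptor_seq_full <- transcript_sequence(genome, acceptor)
  map_rows <- list()

  # ---- donor side ----
  if (!event$donor_bp_in_intron) {
    if (is.na(event$donor_bp_tx) || event$donor_bp_tx < 0L ||
        event$donor_bp_tx >= donor$length) {
      stop("fusion ", event$fusion_id, ": donor breakpoint outside gene body")
    }
    donor_keep <- event$donor_bp_tx + 1L
    donor_seq <- substr(donor_seq_full, 1L, donor_keep)
    intron_d <- NULL
  } else {
    g <- event$donor_bp_genomic
    intron_d <- .intron_containing(donor, g)
    if (is.null(intron_d)) {
      stop("fusion ", event$fusion_id,
           ": intronic donor breakpoint not inside an intron")
    }
    if (donor$strand == "+") {
      exonic_end_g <- intron_d[1] # spliced part ends here
      donor_keep <- genomic_to_tx(donor, exonic_end_g - 1L) + 1L
      ret <- genome_subseq(genome, donor$chrom, intron_d[1], g + 1L)
    } else {
      exonic_start_g <- intron_d[2]
      donor_keep <- genomic_to_tx(donor, exonic_start_g) + 1L
      ret <- reverse_complement(genome_subseq(genome, donor$chrom, g,
                                              intron_d[2]))
    }
    donor_seq <- paste0(substr(donor_seq_full, 1L, donor_keep), ret)
  }
  donor_len <- nchar(donor_seq)

  # ---- acceptor side ----
  if (!event$acceptor_bp_in_intron) {
    if (is.na(event$acceptor_bp_tx) || event$acceptor_bp_tx < 0L ||
        event$acceptor_bp_tx >= acceptor$length) {
      stop("fusion ", event$fusion_id,
           ": acceptor breakpoint outside gene body")
    }
    acc_from <- event$acceptor_bp_tx
    acc_seq <- substr(acceptor_seq_full, acc_from + 1L, acceptor$length)
    intron_a <- NULL
  } else {
    g <- event$acceptor_bp_genomic
    intron_a <- .intron_containing(acceptor, g)
    if (is.null(intron_a)) {
      stop("fusion ", event$fusion_id,
           ": intronic acceptor breakpoint not inside an intron")
    }
    if (acceptor$strand == "+") {
      ret <- genome_subseq(genome, acceptor$chrom, g, intron_a[2])
      acc_from <- genomic_to_tx(acceptor, intron_a[2])
    } else {
      ret <- reverse_complement(genome_subseq(genome, acceptor$chrom,
                                              intron_a[1], g + 1L))
      acc_from <- genomic_to_tx(acceptor, intron_a[1] - 1L)
    }
    acc_seq <- paste0(ret, substr(acceptor_seq_full, acc_from + 1L,
                                  acceptor$length))
  }
  backbone_seq <- paste0(donor_seq, acc_seq)

  # ---- variants into backbone coordinates ----
  if (nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (!is.na(v$parent_id)) next # nested rows follow their parent
      if (v$tx_id == event$donor_tx) {
        keep_tx <- if (event$donor_bp_in_intron) {
          genomic_to_tx(donor, if (donor$strand == "+") intron_d[1] - 1L
                        else intron_d[2]) + 1L
        } else donor_len
        if (v$end <= keep_tx) {
          map_rows[[length(map_rows) + 1L]] <-
            .shift_variant(variants, v, 0L)
        } else if (v$start < keep_tx) {
          warning("fusion ", event$fusion_id, ": donor variant ",
                  v$variant_id, " overlaps the breakpoint; dropped")
        }
      } else if (v$tx_id == event$acceptor_tx && !is.null(event)) {
        a0 <- if (event$acceptor_bp_in_intron) acc_from else
          event$acceptor_bp_tx
        shift <- donor_len +
          (if (event$acceptor_bp_in_intron) nchar(acc_seq) -
             (acceptor$length - a0) else 0L) - a0
        if (v$start >= a0) {
          map_rows[[length(map_rows) + 1L]] <-
            .shift_variant(variants, v, shift)
        } else if (v$end > a0) {
          warning("fusion ", event$fusion_id, ": acceptor variant ",
                  v$variant_id, " overlaps the breakpoint; dropped")
        }
      }
    }
  }
  # intronic variants inside retained introns
  if (!is.null(genomic_variants) && nrow(genomic_variants)) {
    for (i in seq_len(nrow(genomic_variants))) {
      gv <- genomic_variants[i, ]
      if (!is.null(intron_d) && donor$strand == "+" &&
          gv$pos >= intron_d[1] && gv$pos <= event$donor_bp_genomic) {
        off <- (donor_len - (event$donor_bp_genomic - intron_d[1] + 1L)) +
          (gv$pos - intron_d[1])
        map_rows[[length(map_rows) + 1L]] <- variant_table(
          gv$variant_id, event$donor_gene, event$fusion_id,
          off, off + nchar(gv$ref), gv$ref, gv$alt,
          if (nchar(gv$ref) == 1L && nchar(gv$alt) == 1L) "SNV"
          else if (nchar(gv$ref) < nchar(gv$alt)) "INSERTION"
          else "DELETION",
          if (nchar(gv$ref) == 1L && nchar(gv$alt) == 1L) "sSNV" else
            "sIndel"
        )
      }
    }
  }
  bvars <- if (length(map_rows)) {
    do.call(rbind, map_rows)
  } else empty_variant_table()
  # nested rows travel with mapped parents
  nested <- variants[!is.na(variants$parent_id) &
                       variants$parent_id %in% bvars$variant_id, ,
                     drop = FALSE]
  if (nrow(nested)) bvars <- rbind(bvars, nested)

  coding <- donor$is_coding && !is.na(donor$cds_start_tx) &&
    donor$cds_start_tx + 3L <= donor_len
  sec <- integer(0)
  if (length(donor$selenocysteine_tx)) {
    sec <- donor$selenocysteine_tx[donor$selenocysteine_tx + 3L <= donor_len]
  }
  structure(list(
    seq = backbone_seq,
    coding = coding,
    cds_start_tx = if (coding) donor$cds_start_tx else NA_integer_,
    selenocysteine_tx = sec,
    variants = bvars,
    donor_len = donor_len,
    fusion_id = event$fusion_id,
    gene_id = paste0(event$donor_gene, "-", event$acceptor_gene)
  ), class = "fusion_backbone")
}

.shift_variant <- function(variants, v, shift) {
  v$start <- v$start + shift
  v$end <- v$end + shift
  v
}

#' Call variant peptides from a fusion backbone
#'
#' Runs the standard graph pipeline over the joined sequence: under the
#' donor ORF when the donor is coding (chimeric junction peptides
#' included), or as a noncoding novel-ORF search otherwise. All emitted
#' peptides carry the fusion event among their variant annotations.
#'
#' @param backbone A [build_fusion_backbone()] result.
#' @param params A [call_params()].
#' @param canonical_digest Optional canonical peptide set.
#' @return data.frame of peptide entries.
#' @export
call_fusion_peptides <- function(backbone, params = call_params(),
                                 canonical_digest = NULL) {
  model <- if (backbone$coding) {
    structure(list(is_coding = TRUE, cds_start_tx = backbone$cds_start_tx,
                   cds_end_tx = nchar(backbone$seq),
                   selenocysteine_tx = backbone$selenocysteine_tx),
              class = "transcript_model")
  } else NULL
  tier <- if (backbone$coding) "Variant" else "NoncodingVariant"
  out <- call_variant_peptides(
    backbone$seq, model, backbone$variants, params,
    canonical_digest = canonical_digest,
    gene_id = backbone$gene_id, backbone_id = backbone$fusion_id,
    tier = tier, apply_edge_rules = FALSE
  )
  if (nrow(out)) {
    out$variant_ids <- ifelse(
      nzchar(out$variant_ids),
      paste(backbone$fusion_id, out$variant_ids, sep = ";"),
      backbone$fusion_id
    )
  }
  out
}

#' Construct a circular RNA model
#'
#' @param circ_id Stable identifier.
#' @param tx_id,gene_id Host transcript/gene.
#' @param segments Two-column matrix of 0-based half-open transcript-space
#'   intervals (exon or retained-intron pieces, in order); non-empty.
#' @return A list of class `circ_rna_model`.
#' @export
circ_rna_model <- function(circ_id, tx_id = NA_character_,
                           gene_id = NA_character_, segments) {
  segments <- as.matrix(segments)
  storage.mode(segments) <- "integer"
  colnames(segments) <- c("start", "end")
  stopifnot(nrow(segments) >= 1L, all(segments[, 2] > segments[, 1]))
  structure(list(circ_id = circ_id, tx_id = tx_id, gene_id = gene_id,
                 segments = segments),
            class = "circ_rna_model")
}

#' Build a circular RNA backbone
#'
#' Concatenates the circle's segments from the host transcript sequence
#' and maps small variants falling inside the segments into circle
#' coordinates.
#'
#' @param circ A [circ_rna_model()].
#' @param tx_seq Host transcript sequence.
#' @param variants `variant_table` in transcript coordinates.
#' @return List of class `circ_backbone`: `seq` (the circle, back-splice
#'   junction between its last and first base), `variants` (circle
#'   coordinates), `circ_id`.
#' @export
build_circ_backbone <- function(circ, tx_seq,
                                variants = empty_variant_table()) {
  segs <- circ$segments
  parts <- character(nrow(segs))
  offsets <- integer(nrow(segs))
  off <- 0L
  for (i in seq_len(nrow(segs))) {
    parts[i] <- substr(tx_seq, segs[i, 1] + 1L, segs[i, 2])
    offsets[i] <- off
    off <- off + (segs[i, 2] - segs[i, 1])
  }
  circ_seq <- paste(parts, collapse = "")
  if (nchar(circ_seq) < 1L) stop("circRNA ", circ$circ_id, ": empty circle")
  rows <- list()
  if (nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (!is.na(v$parent_id)) next
      for (j in seq_len(nrow(segs))) {
        if (v$start >= segs[j, 1] && v$end <= segs[j, 2] &&
            !(v$start == v$end && v$start == segs[j, 1])) {
          rows[[length(rows) + 1L]] <-
            .shift_variant(variants, v, offsets[j] - segs[j, 1])
          break
        }
      }
    }
  }
  structure(list(
    seq = circ_seq,
    variants = if (length(rows)) do.call(rbind, rows)
               else empty_variant_table(),
    circ_id = circ$circ_id,
    gene_id = circ$gene_id
  ), class = "circ_backbone")
}

#' Call peptides from a circular RNA backbone
#'
#' A circle is read by the ribosome through the back-splice junction; if
#' its length is not a multiple of three each traversal shifts the frame,
#' and after three traversals the amino-acid sequence repeats. The circle
#' is linearized as four concatenated copies so that every window of up to
#' three traversals exists linearly; novel ORF starts (methionines) are
#' taken from the first traversal and each ORF is capped at three circle
#' lengths. Because a variant is a property of the molecule, a chosen
#' variant subset is applied to every traversal consistently: the caller
#' enumerates compatible subsets at the circle level and runs the graph
#' pipeline per edited circle. Peptides are deduplicated across the
#' periodic repeats.
#'
#' @param backbone A [build_circ_backbone()] result.
#' @param params A [call_params()].
#' @param canonical_digest Optional canonical peptide set.
#' @return data.frame of peptide entries (tier `CircularRNA`).
#' @export
call_circ_peptides <- function(backbone, params = call_params(),
                               canonical_digest = NULL) {
  subsets <- .compatible_subsets(
    backbone$variants[is.na(backbone$variants$parent_id), , drop = FALSE],
    include_empty = TRUE
  )
  out <- list()
  for (s in subsets) {
    full <- if (nrow(s)) {
      rbind(s, backbone$variants[!is.na(backbone$variants$parent_id) &
                                   backbone$variants$parent_id %in%
                                     s$variant_id, , drop = FALSE])
    } else s
    circ2 <- apply_variants_to_sequence(backbone$seq, full)$seq
    L2 <- nchar(circ2)
    lin <- strrep(circ2, 4L)
    p2 <- params
    p2$orf_start_max_nt <- L2
    p2$orf_cap_nt <- 3L * L2
    ent <- call_variant_peptides(
      lin, NULL, empty_variant_table(), p2,
      canonical_digest = canonical_digest,
      gene_id = backbone$gene_id, backbone_id = backbone$circ_id,
      tier = "CircularRNA", apply_edge_rules = FALSE
    )
    if (nrow(ent)) {
      vid <- paste(sort(c(backbone$circ_id, full$variant_id)),
                   collapse = ";")
      ent$variant_ids <- vid
      out[[length(out) + 1L]] <- ent
    }
  }
  if (!length(out)) return(.empty_entries())
  unique(do.call(rbind, out))
}
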