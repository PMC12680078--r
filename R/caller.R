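# Calling variant peptides: end-to-end traversal of one transcript
# backbone, canonical-proteome exclusion, source annotation, database
# tiering and FASTA output.

.tier_order <- c("Variant", "Noncoding", "NoncodingVariant", "CircularRNA",
                 "AltTranslation")

#' Peptide calling parameters
#'
#' @param enzyme Protease name or [enzyme_spec()].
#' @param max_miscleavage Maximum internal miscleavages; defaults to the
#'   enzyme's standard setting (2 for trypsin/Lys-C/Arg-C, 3 for
#'   Glu-C/Asp-N, 4 for chymotrypsin).
#' @param min_length,max_length Peptide length bounds (default 7-25).
#' @param pop_cutoff,pop_x Pop-and-collapse: applied when a bubble exceeds
#'   `pop_cutoff` member nodes, popping `pop_x` residues.
#' @param w_to_f_multi Emit multi-site W>F substitutant combinations
#'   (default: single site per copy).
#' @param orf_start_max_nt,orf_cap_nt Internal bounds used by the circular
#'   RNA caller (ORF starts restricted to the first traversal; each ORF
#'   capped at three circle lengths).
#' @return A list of class `call_params`.
#' @export
call_params <- function(enzyme = "trypsin", max_miscleavage = NULL,
                        min_length = 7L, max_length = 25L,
                        pop_cutoff = 32L, pop_x = 5L,
                        w_to_f_multi = FALSE,
                        orf_start_max_nt = NULL, orf_cap_nt = NULL) {
  enzyme <- enzyme_spec(enzyme)
  if (is.null(max_miscleavage)) max_miscleavage <- enzyme$max_miscleavage
  stopifnot(max_miscleavage >= 0L, min_length >= 1L,
            max_length >= min_length, pop_cutoff >= 1L, pop_x >= 0L)
  structure(list(
    enzyme = enzyme, max_miscleavage = as.integer(max_miscleavage),
    min_length = as.integer(min_length), max_length = as.integer(max_length),
    pop_cutoff = as.integer(pop_cutoff), pop_x = as.integer(pop_x),
    w_to_f_multi = isTRUE(w_to_f_multi),
    orf_start_max_nt = orf_start_max_nt, orf_cap_nt = orf_cap_nt
  ), class = "call_params")
}

#' Digest a canonical proteome into a peptide lookup set
#'
#' @param proteome Named character vector of protein sequences.
#' @param params A [call_params()]; the same enzyme/miscleavage/length
#'   settings used for calling must be used here.
#' @return Character vector of unique canonical peptides.
#' @export
canonical_digest_set <- function(proteome, params = call_params()) {
  if (!length(proteome)) return(character(0))
  unique(unlist(lapply(proteome, function(p) {
    p <- gsub("\\*", "", p)
    digest_protein(p, params$enzyme, max_mc = params$max_miscleavage,
                   min_len = params$min_length, max_len = params$max_length)
  }), use.names = FALSE))
}

#' Remove peptides producible from the canonical proteome
#'
#' @param entries Peptide data.frame with a `peptide` column.
#' @param canonical_digest Peptides from [canonical_digest_set()].
#' @return Filtered data.frame.
#' @export
filter_canonical <- function(entries, canonical_digest) {
  if (!nrow(entries) || !length(canonical_digest)) return(entries)
  entries[!entries$peptide %in% canonical_digest, , drop = FALSE]
}

.empty_entries <- function() {
  data.frame(peptide = character(0), tier = character(0),
             gene_id = character(0), backbone_id = character(0),
             variant_ids = character(0), miscleavages = integer(0),
             orf_start = character(0), stringsAsFactors = FALSE)
}

#' Call non-canonical peptides from one transcript backbone
#'
#' Runs the full graph pipeline for a single backbone: edge-case variant
#' exclusion, transcript variant graph construction with three-frame
#' modeling, bubble alignment and codon adjustment, translation, cleavage
#' graph conversion, stage-and-call traversal with miscleavage extension,
#' and canonical-proteome exclusion. For backbones with a known ORF the
#' graph is rooted at the annotated start codon; noncoding backbones are
#' scanned for novel ORFs (any methionine in any frame, start-gain
#' included).
#'
#' @param tx_seq Transcript nucleotide sequence (spliced, 5'->3').
#' @param tx_model A [transcript_model()], or `NULL` for a bare noncoding
#'   backbone.
#' @param variants A `variant_table` in transcript coordinates.
#' @param params A [call_params()].
#' @param canonical_digest Optional canonical peptide set for exclusion.
#' @param gene_id,backbone_id Identifiers recorded in the output sources.
#' @param tier Tier label override (e.g. `"CircularRNA"`); by default
#'   inferred (Variant for coding backbones, Noncoding/NoncodingVariant for
#'   noncoding ones).
#' @param apply_edge_rules Apply [exclude_edge_case_variants()] first.
#' @return data.frame of peptide entries.
#' @export
call_variant_peptides <- function(tx_seq, tx_model = NULL,
                                  variants = empty_variant_table(),
                                  params = call_params(),
                                  canonical_digest = NULL,
                                  gene_id = "GENE", backbone_id = "TX",
                                  tier = NULL, apply_edge_rules = TRUE) {
  coding <- !is.null(tx_model) && isTRUE(tx_model$is_coding)
  if (apply_edge_rules && !is.null(tx_model) && nrow(variants)) {
    variants <- exclude_edge_case_variants(variants, tx_model)$kept
  }
  if (nrow(variants)) validate_variants_against_sequence(variants, tx_seq)
  orf0 <- if (coding) tx_model$cds_start_tx else 0L
  sec <- if (!is.null(tx_model)) tx_model$selenocysteine_tx else integer(0)
  seq2 <- substr(tx_seq, orf0 + 1L, nchar(tx_seq))
  v2 <- variants
  if (nrow(v2)) {
    top <- is.na(v2$parent_id)
    v2$start[top] <- v2$start[top] - orf0
    v2$end[top] <- v2$end[top] - orf0
    if (any(v2$start[top] < 0L)) {
      stop("variants 5' of the ORF must be excluded before calling")
    }
  }
  sec2 <- sec[sec >= orf0] - orf0
  if (!nchar(seq2)) return(.empty_entries())
  pvg <- translate_graph(seq2, coding, v2, sec_positions = sec2,
                         pop_cutoff = params$pop_cutoff,
                         pop_x = params$pop_x)
  pcg <- to_cleavage_graph(pvg, params$enzyme)
  raw <- extend_miscleavages(pcg, params)
  if (!nrow(raw)) return(.empty_entries())
  if (!is.null(canonical_digest)) {
    raw <- filter_canonical(raw, canonical_digest)
  }
  if (!nrow(raw)) return(.empty_entries())
  tier_of <- if (!is.null(tier)) {
    rep(tier, nrow(raw))
  } else if (coding) {
    rep("Variant", nrow(raw))
  } else {
    ifelse(raw$n_variants > 0L, "NoncodingVariant", "Noncoding")
  }
  out <- data.frame(
    peptide = raw$peptide, tier = tier_of,
    gene_id = gene_id, backbone_id = backbone_id,
    variant_ids = raw$variant_ids, miscleavages = raw$miscleavages,
    orf_start = if (coding) "0" else "?",
    stringsAsFactors = FALSE
  )
  unique(out)
}

#' Deduplicate peptide entries and union their sources
#'
#' One entry per unique sequence; all (gene, backbone, variant
#' combination, ORF) sources are retained so that redundancy across
#' variant combinations and backbones is documented rather than
#' duplicated. The entry tier is the highest-priority tier among its
#' sources (Variant > Noncoding > NoncodingVariant > CircularRNA >
#' AltTranslation).
#'
#' @param entries data.frame from [call_variant_peptides()] (possibly
#'   concatenated across backbones).
#' @return data.frame with columns `peptide`, `tier`, `sources`
#'   (deterministic, space-joined).
#' @export
dedupe_and_annotate <- function(entries) {
  if (!nrow(entries)) {
    return(data.frame(peptide = character(0), tier = character(0),
                      sources = character(0), stringsAsFactors = FALSE))
  }
  src <- paste0(entries$gene_id, "|", entries$backbone_id, "|",
                ifelse(nzchar(entries$variant_ids), entries$variant_ids, "-"),
                "|ORF", entries$orf_start, "|", entries$tier)
  sp <- split(seq_len(nrow(entries)), entries$peptide)
  peps <- names(sp)
  tiers <- vapply(sp, function(i) {
    .tier_order[min(match(entries$tier[i], .tier_order))]
  }, character(1))
  sources <- vapply(sp, function(i) {
    paste(sort(unique(src[i])), collapse = " ")
  }, character(1))
  out <- data.frame(peptide = peps, tier = unname(tiers),
                    sources = unname(sources), stringsAsFactors = FALSE)
  out[order(out$peptide), , drop = FALSE]
}

#' Split a deduplicated peptide database into tiers
#'
#' Disjoint partition by tier label; entries whose sources span multiple
#' tiers were already assigned their highest-priority tier by
#' [dedupe_and_annotate()].
#'
#' @param db data.frame from [dedupe_and_annotate()].
#' @return Named list of data.frames, one per tier present.
#' @export
split_tiers <- function(db) {
  if (!nrow(db)) return(list())
  bad <- !db$tier %in% .tier_order
  if (any(bad)) {
    stop("unclassifiable entries: ",
         paste(utils::head(db$sources[bad], 3), collapse = "; "))
  }
  out <- split(db, factor(db$tier, levels = .tier_order))
  out[vapply(out, nrow, integer(1)) > 0L]
}

#' Merge peptide databases before tier splitting
#'
#' Unions entry-level databases (e.g. across samples of one multiplex) and
#' re-deduplicates, so shared peptides carry the union of their sources.
#'
#' @param ... data.frames from [call_variant_peptides()] or
#'   already-deduplicated databases (with a `sources` column).
#' @return A deduplicated database (as [dedupe_and_annotate()]).
#' @export
merge_peptide_databases <- function(...) {
  dbs <- list(...)
  dbs <- dbs[vapply(dbs, nrow, integer(1)) > 0L]
  if (!length(dbs)) return(dedupe_and_annotate(.empty_entries()))
  norm <- lapply(dbs, function(d) {
    if ("sources" %in% names(d)) {
      d
    } else {
      dedupe_and_annotate(d)
    }
  })
  all <- do.call(rbind, norm)
  sp <- split(seq_len(nrow(all)), all$peptide)
  out <- data.frame(
    peptide = names(sp),
    tier = vapply(sp, function(i) {
      .tier_order[min(match(all$tier[i], .tier_order))]
    }, character(1)),
    sources = vapply(sp, function(i) {
      paste(sort(unique(unlist(strsplit(all$sources[i], " ", fixed = TRUE)))),
            collapse = " ")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$peptide), , drop = FALSE]
}

#' Alternative-translation peptides
#'
#' Two modes operating on the canonical proteome:
#' `selenocysteine_termination` emits peptides from the isoform of each
#' selenoprotein truncated at its first selenocysteine (UGA read as stop
#' instead of Sec); `w_to_f` emits copies of tryptophan-containing
#' canonical peptides with W->F substitutions (one site per copy unless
#' `params$w_to_f_multi`). Peptides producible from the canonical digest
#' are excluded.
#'
#' @param proteome Named character vector of canonical protein sequences
#'   (selenoproteins contain `U`).
#' @param mode `"selenocysteine_termination"` or `"w_to_f"`.
#' @param params A [call_params()].
#' @param canonical_digest Peptide set from [canonical_digest_set()];
#'   computed from `proteome` when missing.
#' @return data.frame of peptide entries (tier `AltTranslation`).
#' @export
call_alt_translation <- function(proteome,
                                 mode = c("selenocysteine_termination",
                                          "w_to_f"),
                                 params = call_params(),
                                 canonical_digest = NULL) {
  if (!mode[1] %in% c("selenocysteine_termination", "w_to_f")) {
    stop("unknown alternative-translation mode '", mode[1], "'")
  }
  mode <- match.arg(mode)
  if (is.null(canonical_digest)) {
    canonical_digest <- canonical_digest_set(proteome, params)
  }
  rows <- list()
  add <- function(pep, name, vid) {
    rows[[length(rows) + 1L]] <<- data.frame(
      peptide = pep, tier = "AltTranslation", gene_id = name,
      backbone_id = name, variant_ids = vid, miscleavages = NA_integer_,
      orf_start = "0", stringsAsFactors = FALSE
    )
  }
  if (mode == "selenocysteine_termination") {
    for (name in names(proteome)) {
      p <- proteome[[name]]
      u <- regexpr("U", p, fixed = TRUE)
      if (u == -1L) next
      trunc <- substr(p, 1L, u - 1L)
      peps <- digest_protein(trunc, params$enzyme,
                             max_mc = params$max_miscleavage,
                             min_len = params$min_length,
                             max_len = params$max_length)
      peps <- setdiff(peps, canonical_digest)
      for (pep in peps) add(pep, name, "SecTermination")
    }
  } else {
    for (name in names(proteome)) {
      p <- gsub("\\*", "", proteome[[name]])
      peps <- digest_protein(p, params$enzyme,
                             max_mc = params$max_miscleavage,
                             min_len = params$min_length,
                             max_len = params$max_length)
      peps <- peps[grepl("W", peps, fixed = TRUE)]
      for (pep in peps) {
        w_pos <- gregexpr("W", pep, fixed = TRUE)[[1]]
        subs <- if (params$w_to_f_multi) {
          lapply(.nonempty_subsets(w_pos), identity)
        } else {
          as.list(w_pos)
        }
        for (s in subs) {
          cand <- pep
          for (pos in s) substr(cand, pos, pos) <- "F"
          if (!cand %in% canonical_digest) {
            add(cand, name, paste0("W>F@", paste(s, collapse = ",")))
          }
        }
      }
    }
  }
  if (!length(rows)) return(.empty_entries())
  unique(do.call(rbind, rows))
}

.nonempty_subsets <- function(x) {
  n <- length(x)
  if (n > 12L) stop("too many sites for multi-site substitutants")
  out <- list()
  for (mask in seq_len(2L^n - 1L)) {
    out[[mask]] <- x[bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L]
  }
  out
}

#' Write a peptide database to FASTA
#'
#' Headers follow the grammar
#' `>{gene}|{backbone}|{variants}|ORF{start}|{tier}` with multiple sources
#' space-joined; records are written in deterministic (sequence) order so
#' identical inputs produce byte-identical files.
#'
#' @param db data.frame from [dedupe_and_annotate()] (or entries, which are
#'   deduplicated first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(db, path) {
  if (!"sources" %in% names(db)) db <- dedupe_and_annotate(db)
  db <- db[order(db$peptide), , drop = FALSE]
  lines <- character(2L * nrow(db))
  if (nrow(db)) {
    lines[seq(1L, by = 2L, length.out = nrow(db))] <-
      paste0(">", db$sources)
    lines[seq(2L, by = 2L, length.out = nrow(db))] <- db$peptide
  }
  writeLines(lines, path)
  invisible(path)
}
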