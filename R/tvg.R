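# Transcript variant graph (TVG).
#
# The TVG holds three linear reference chains (reading frames offset by
# 0/1/2 nt from the sequence 5' end), into which variant nodes are spliced
# by breaking reference nodes at the variant span and attaching an
# alternative-sequence node. In-frame variants close back into the same
# frame chain; frameshifting variants close into the chain of the outgoing
# frame given by (incoming + S_ref - S_alt) mod 3.
#
# Nodes live in an environment so surgery is cheap; edges are typed
# (variant_open / variant_close / reference_elongation).

.tvg_new_node <- function(tvg, kind, seq, frame, start, end,
                          variant_id = NA_character_,
                          subgraph_id = NA_character_) {
  e <- tvg$env
  id <- e$next_id
  e$next_id <- id + 1L
  e$nodes[[as.character(id)]] <- list(
    id = id, kind = kind, seq = seq, frame = frame,
    start = start, end = end, variant_id = variant_id,
    subgraph_id = subgraph_id,
    out = integer(0), out_type = character(0),
    inn = integer(0)
  )
  id
}

.tvg_get <- function(tvg, id) tvg$env$nodes[[as.character(id)]]
.tvg_set <- function(tvg, node) {
  tvg$env$nodes[[as.character(node$id)]] <- node
  invisible(node$id)
}

.tvg_add_edge <- function(tvg, from, to, type) {
  a <- .tvg_get(tvg, from)
  if (!to %in% a$out) {
    a$out <- c(a$out, to)
    a$out_type <- c(a$out_type, type)
    .tvg_set(tvg, a)
    b <- .tvg_get(tvg, to)
    b$inn <- c(b$inn, from)
    .tvg_set(tvg, b)
  }
  invisible(NULL)
}

#' Initialize a transcript variant graph
#'
#' Creates the three linear root nodes holding the full sequence offset by
#' 0, 1 and 2 nucleotides from its 5' end — the three reading-frame
#' subgraphs. Frames whose offset exceeds the sequence length are marked
#' degenerate (empty).
#'
#' @param tx_seq Transcript nucleotide sequence (non-empty).
#' @param tx_model Optional [transcript_model()]; sets `has_known_orf`.
#' @return An object of class `tvg`.
#' @export
init_tvg <- function(tx_seq, tx_model = NULL) {
  stopifnot(is.character(tx_seq), length(tx_seq) == 1L)
  if (nchar(tx_seq) == 0L) stop("init_tvg(): empty transcript sequence")
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$next_id <- 1L
  env$variant_registry <- empty_variant_table()
  tvg <- structure(list(
    env = env, seq = tx_seq, length = nchar(tx_seq),
    has_known_orf = !is.null(tx_model) && isTRUE(tx_model$is_coding),
    roots = integer(3)
  ), class = "tvg")
  L <- nchar(tx_seq)
  for (k in 0:2) {
    s <- if (k < L) substr(tx_seq, k + 1L, L) else ""
    tvg$roots[k + 1L] <- .tvg_new_node(tvg, "ref", s, k, min(k, L), L)
  }
  tvg
}

#' @export
print.tvg <- function(x, ...) {
  nn <- length(x$env$nodes)
  cat(sprintf("<tvg: %d nt, %d node(s), %s ORF>\n", x$length, nn,
              if (x$has_known_orf) "known" else "unknown"))
  invisible(x)
}

#' Outgoing reading frame after a variant
#'
#' The reading frame of the chain a variant node closes into:
#' `(incoming_frame + S_ref - S_alt) mod 3`, with a floor mod so the result
#' is always in `{0, 1, 2}` (insertions make the difference negative). The
#' incoming frame is returned unchanged when the net length change is a
#' multiple of three.
#'
#' @param s_ref,s_alt Reference and alternative allele lengths (>= 0).
#' @param incoming_frame Frame index in `{0, 1, 2}`.
#' @return Outgoing frame index.
#' @export
outgoing_frame <- function(s_ref, s_alt, incoming_frame = 0L) {
  stopifnot(all(s_ref >= 0L), all(s_alt >= 0L),
            all(incoming_frame %in% 0:2))
  (incoming_frame + s_ref - s_alt) %% 3L
}

# Split the reference node of `frame` at sequence position `pos` (0-based,
# in the coordinate system of tvg$seq). Returns invisibly. No-op when a
# node boundary already falls at pos.
.tvg_split_ref <- function(tvg, frame, pos) {
  for (nd in tvg$env$nodes) {
    if (nd$kind != "ref" || nd$frame != frame || !is.na(nd$subgraph_id)) next
    if (nd$start < pos && pos < nd$end) {
      left <- nd
      left$seq <- substr(tvg$seq, nd$start + 1L, pos)
      left$end <- pos
      right_id <- .tvg_new_node(tvg, "ref",
                                substr(tvg$seq, pos + 1L, nd$end),
                                frame, pos, nd$end)
      right <- .tvg_get(tvg, right_id)
      right$out <- nd$out
      right$out_type <- nd$out_type
      .tvg_set(tvg, right)
      for (succ in nd$out) {
        s <- .tvg_get(tvg, succ)
        s$inn[s$inn == nd$id] <- right_id
        .tvg_set(tvg, s)
      }
      left$out <- integer(0)
      left$out_type <- character(0)
      .tvg_set(tvg, left)
      .tvg_add_edge(tvg, left$id, right_id, "reference_elongation")
      return(invisible(NULL))
    }
  }
  invisible(NULL)
}

# Reference node in `frame` that starts at pos (after splitting), or NULL.
.tvg_ref_at <- function(tvg, frame, pos, boundary = c("start", "end")) {
  boundary <- match.arg(boundary)
  for (nd in tvg$env$nodes) {
    if (nd$kind != "ref" || nd$frame != frame || !is.na(nd$subgraph_id)) next
    if (boundary == "start" && nd$start == pos) return(nd)
    if (boundary == "end" && nd$end == pos) return(nd)
  }
  NULL
}

# Frames into which variants are materialized. All three chains are used
# for unknown-ORF transcripts and whenever any frameshifting variant exists
# (subgraphs of the outgoing frames must then carry downstream variants);
# otherwise only the canonical chain is needed. Materializing a chain that
# is never reached changes nothing downstream: the caller only traverses
# nodes reachable from a valid ORF.
.tvg_frames_for <- function(tvg, variants) {
  if (!tvg$has_known_orf) return(0:2)
  if (!nrow(variants)) return(0L)
  shift <- (nchar(variants$ref) - nchar(variants$alt)) %% 3L
  if (any(shift != 0L)) 0:2 else 0L
}

#' Incorporate a variant into a transcript variant graph
#'
#' Breaks the reference chain at the variant's start and end positions and
#' attaches a node carrying the alternative sequence, with a
#' `variant_open` edge from the upstream reference node and a
#' `variant_close` edge to the downstream reference node. In-frame variants
#' close into the same frame chain; frameshifting variants close into the
#' chain given by [outgoing_frame()]. For unknown-ORF transcripts the
#' variant is applied to all three frame chains; for known-ORF transcripts
#' it is applied to the canonical chain, plus the other chains when
#' frameshifting variants are in play (`frames` argument).
#'
#' @param tvg A `tvg`.
#' @param v A single-row [variant_table()] (or coercible list).
#' @param frames Frame chains to apply the variant to; defaults to the
#'   chains materialized for this graph's variant set.
#' @return The modified `tvg`, invisibly (the graph is mutated in place).
#' @export
apply_variant <- function(tvg, v, frames = NULL) {
  if (is.data.frame(v)) v <- as.list(v[1, ])
  if (v$start < 0L || v$end > tvg$length) {
    stop("variant ", v$variant_id, ": span [", v$start, ", ", v$end,
         ") outside transcript [0, ", tvg$length, ")")
  }
  if (is.null(frames)) {
    frames <- if (tvg$has_known_orf) 0L else 0:2
  }
  tvg$env$variant_registry <- rbind(tvg$env$variant_registry,
                                    as.data.frame(v, stringsAsFactors = FALSE))
  s_ref <- nchar(v$ref)
  s_alt <- nchar(v$alt)
  for (f in frames) {
    root <- .tvg_get(tvg, tvg$roots[f + 1L])
    if (v$start < root$start) next # variant 5' of this frame's offset
    .tvg_split_ref(tvg, f, v$start)
    out_f <- outgoing_frame(s_ref, s_alt, f)
    .tvg_split_ref(tvg, out_f, v$end)
    up <- .tvg_ref_at(tvg, f, v$start, "end")
    down <- .tvg_ref_at(tvg, out_f, v$end, "start")
    alt_id <- .tvg_new_node(tvg, "alt", v$alt, f, v$start, v$end,
                            variant_id = v$variant_id)
    if (!is.null(up)) .tvg_add_edge(tvg, up$id, alt_id, "variant_open")
    if (!is.null(down)) .tvg_add_edge(tvg, alt_id, down$id, "variant_close")
  }
  invisible(tvg)
}

#' Incorporate an alternative-splicing variant as a subgraph
#'
#' Large insertions and substitutions from alternative splicing are added
#' like ordinary variants, but their inserted sequence forms a subgraph of
#' reference-typed nodes (tagged with the event's `subgraph_id`) that can
#' itself carry additional small variants: nested records (rows of
#' `variants` whose `parent_id` equals the event's `variant_id`, with
#' coordinates relative to the inserted sequence) split the subgraph around
#' their own alt nodes. Nesting deeper than one level is rejected.
#'
#' @param tvg A `tvg`.
#' @param v The alternative-splicing variant (single row).
#' @param nested Optional `variant_table` of nested records.
#' @param frames As in [apply_variant()].
#' @return The modified `tvg`, invisibly.
#' @export
apply_alt_splice <- function(tvg, v, nested = NULL, frames = NULL) {
  if (is.data.frame(v)) v <- as.list(v[1, ])
  if (!is.null(nested) && nrow(nested)) {
    if (any(!is.na(nested$parent_id) &
            nested$parent_id %in% nested$variant_id[!is.na(nested$parent_id)])) {
      stop("apply_alt_splice(): nested subgraphs beyond depth 1 are not ",
           "supported")
    }
    nested <- nested[!is.na(nested$parent_id) &
                       nested$parent_id == v$variant_id, , drop = FALSE]
  }
  if (is.null(frames)) frames <- if (tvg$has_known_orf) 0L else 0:2
  tvg$env$variant_registry <- rbind(
    tvg$env$variant_registry,
    as.data.frame(v, stringsAsFactors = FALSE),
    if (!is.null(nested) && nrow(nested)) nested
  )
  s_ref <- nchar(v$ref)
  s_alt <- nchar(v$alt)
  for (f in frames) {
    root <- .tvg_get(tvg, tvg$roots[f + 1L])
    if (v$start < root$start) next
    .tvg_split_ref(tvg, f, v$start)
    out_f <- outgoing_frame(s_ref, s_alt, f)
    .tvg_split_ref(tvg, out_f, v$end)
    up <- .tvg_ref_at(tvg, f, v$start, "end")
    down <- .tvg_ref_at(tvg, out_f, v$end, "start")
    # build the inserted-sequence subgraph: reference-typed nodes split
    # around any nested variants
    cuts <- 0L
    if (!is.null(nested) && nrow(nested)) {
      cuts <- sort(unique(c(0L, nested$start, nested$end, nchar(v$alt))))
    } else {
      cuts <- c(0L, nchar(v$alt))
    }
    seg_ids <- integer(0)
    for (i in seq_len(length(cuts) - 1L)) {
      seg <- substr(v$alt, cuts[i] + 1L, cuts[i + 1L])
      seg_ids <- c(seg_ids, .tvg_new_node(
        tvg, "ref", seg, f, NA_integer_, NA_integer_,
        subgraph_id = v$variant_id
      ))
    }
    for (i in seq_len(max(0L, length(seg_ids) - 1L))) {
      .tvg_add_edge(tvg, seg_ids[i], seg_ids[i + 1L],
                    "reference_elongation")
    }
    if (!is.null(nested) && nrow(nested)) {
      for (j in seq_len(nrow(nested))) {
        nv <- nested[j, ]
        from <- seg_ids[which(cuts == nv$start)[1] - 1L]
        to_i <- which(cuts == nv$end)[1]
        to <- if (to_i <= length(seg_ids)) seg_ids[to_i] else NA_integer_
        nid <- .tvg_new_node(tvg, "alt", nv$alt, f, nv$start, nv$end,
                             variant_id = nv$variant_id,
                             subgraph_id = v$variant_id)
        if (!is.na(from)) .tvg_add_edge(tvg, from, nid, "variant_open")
        if (!is.na(to)) .tvg_add_edge(tvg, nid, to, "variant_close")
      }
    }
    if (!is.null(up)) {
      .tvg_add_edge(tvg, up$id, seg_ids[1], "variant_open")
    }
    if (!is.null(down) && length(seg_ids)) {
      .tvg_add_edge(tvg, seg_ids[length(seg_ids)], down$id, "variant_close")
    }
  }
  invisible(tvg)
}

#' Reconstruct the reference path of one frame chain
#'
#' Concatenates the reference (non-subgraph) nodes of a frame chain in
#' coordinate order. After any number of variant applications this must
#' reproduce the transcript sequence with the frame offset trimmed.
#'
#' @param tvg A `tvg`.
#' @param frame Frame index.
#' @return Nucleotide string.
#' @export
reference_path_sequence <- function(tvg, frame = 0L) {
  nds <- Filter(function(n) {
    n$kind == "ref" && n$frame == frame && is.na(n$subgraph_id)
  }, tvg$env$nodes)
  if (!length(nds)) return("")
  ord <- order(vapply(nds, `[[`, integer(1), "start"))
  paste(vapply(nds[ord], `[[`, character(1), "seq"), collapse = "")
}

#' Exclude variants falling under the biological edge-case rules
#'
#' For transcripts with a known ORF: variants overlapping the annotated
#' start codon are excluded (whether and where translation would still
#' initiate is unknowable), variants strictly 5' of the ORF or strictly 3'
#' of the annotated stop codon are excluded (they cannot alter the protein
#' under the stop/start rules), and stop-codon-altering variants are kept
#' (translation simply never extends past the transcript end). Variants
#' whose annotation consequence marks a splice site
#' (`splice_donor/acceptor/...`) are excluded for all transcripts.
#'
#' @param variants A `variant_table`.
#' @param tx_model A `transcript_model`.
#' @return A list with elements `kept` (a `variant_table`) and `excluded`
#'   (data.frame of `variant_id`, `reason`).
#' @export
exclude_edge_case_variants <- function(variants, tx_model) {
  reason <- rep(NA_character_, nrow(variants))
  splice <- !is.na(variants$consequence) &
    grepl("splice_(donor|acceptor|region)", variants$consequence)
  reason[splice] <- "splice-site-altering"
  if (isTRUE(tx_model$is_coding)) {
    cs <- tx_model$cds_start_tx
    stop_end <- tx_model$cds_end_tx + 3L
    top <- is.na(variants$parent_id)
    start_hit <- top & variants$start < cs + 3L & variants$end > cs
    reason[is.na(reason) & start_hit] <- "start-codon-altering"
    five_prime <- top & variants$end <= cs
    reason[is.na(reason) & five_prime] <- "5'-of-ORF"
    three_prime <- top & variants$start >= stop_end
    reason[is.na(reason) & three_prime] <- "3'-of-stop-codon"
  }
  # nested records follow their parent
  if (any(!is.na(variants$parent_id))) {
    dropped <- variants$variant_id[!is.na(reason)]
    orphan <- !is.na(variants$parent_id) & variants$parent_id %in% dropped
    reason[is.na(reason) & orphan] <- "parent-excluded"
  }
  keep <- is.na(reason)
  list(
    kept = variants[keep, , drop = FALSE],
    excluded = data.frame(
      variant_id = variants$variant_id[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
}
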