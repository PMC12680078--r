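# Shared variant-application semantics.
#
# Both the graph engine and the brute-force oracle must agree on (a) when
# two variants are compatible (pairwise non-overlapping transcript spans)
# and (b) the deterministic order in which a compatible subset is applied
# to a sequence. These are format-level conventions, factored here; the
# enumeration algorithms that consume them are independent.

# Pairwise compatibility of two transcript spans (0-based half-open).
# Zero-width (insertion) spans at the same position are incompatible
# because their application order would be ambiguous.
.spans_compatible <- function(s1, e1, s2, e2) {
  if (s1 < e2 && s2 < e1) return(FALSE)
  if (s1 == s2 && e1 == s1 && e2 == s2) return(FALSE)
  TRUE
}

#' Pairwise compatibility of variant records
#'
#' Two variants may co-occur on one haplotype path when their replaced
#' reference spans do not overlap. A nested record is compatible with its
#' own parent, incompatible with overlapping siblings of the same parent,
#' and only applicable when the parent is applied.
#'
#' @param variants A `variant_table`.
#' @return Logical matrix `n x n` of pairwise compatibility.
#' @export
variant_compatibility <- function(variants) {
  n <- nrow(variants)
  m <- matrix(TRUE, n, n)
  if (n < 2L) return(m)
  tx <- variants$tx_id
  pid <- variants$parent_id
  s <- variants$start
  e <- variants$end
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!identical(tx[i], tx[j])) next # different coordinate spaces
      same_space <- (is.na(pid[i]) && is.na(pid[j])) ||
        identical(pid[i], pid[j])
      ok <- if (same_space) {
        .spans_compatible(s[i], e[i], s[j], e[j])
      } else TRUE # nested records of different parents never collide
      m[i, j] <- ok
      m[j, i] <- ok
    }
  }
  m
}

# Deterministic application order: descending start, then descending end.
.edit_order <- function(df) {
  order(df$start, df$end, decreasing = TRUE, method = "radix")
}

# Realize a parent's alternative sequence by applying its chosen nested
# records (coordinates relative to the parent's alt).
.realize_alt <- function(parent_alt, nested) {
  if (is.null(nested) || !nrow(nested)) return(parent_alt)
  s <- parent_alt
  for (i in .edit_order(nested)) {
    v <- nested[i, ]
    s <- paste0(substr(s, 1L, v$start), v$alt,
                substr(s, v$end + 1L, nchar(s)))
  }
  s
}

#' Apply a compatible variant subset to a sequence by string editing
#'
#' Applies top-level records in the canonical order (descending start,
#' then descending end); nested records are first realized into their
#' parent's alternative sequence. Annotated positions (e.g. selenocysteine
#' codon starts) are remapped through the edits: positions overlapped by a
#' chosen span are dropped, others are shifted by the net length change of
#' all edits 5' of them.
#'
#' @param seq Reference nucleotide sequence.
#' @param variants Chosen subset (`variant_table`, may include nested rows).
#' @param positions Optional 0-based positions to remap.
#' @return List with `seq` (edited sequence) and `positions` (remapped,
#'   dropped positions removed).
#' @export
apply_variants_to_sequence <- function(seq, variants,
                                       positions = integer(0)) {
  if (is.null(variants) || !nrow(variants)) {
    return(list(seq = seq, positions = positions))
  }
  top <- variants[is.na(variants$parent_id), , drop = FALSE]
  out <- seq
  alt_real <- vapply(seq_len(nrow(top)), function(i) {
    nested <- variants[!is.na(variants$parent_id) &
                         variants$parent_id == top$variant_id[i], ,
                       drop = FALSE]
    .realize_alt(top$alt[i], nested)
  }, character(1))
  ord <- .edit_order(top)
  for (i in ord) {
    out <- paste0(substr(out, 1L, top$start[i]), alt_real[i],
                  substr(out, top$end[i] + 1L, nchar(out)))
  }
  if (length(positions)) {
    keep <- !vapply(positions, function(p) {
      any(top$start < p + 1L & top$end > p) # overlapped by a span
    }, logical(1))
    shifted <- vapply(positions, function(p) {
      before <- top$end <= p
      p + sum(nchar(alt_real[before]) - (top$end[before] - top$start[before]))
    }, integer(1))
    positions <- shifted[keep]
  }
  list(seq = out, positions = positions)
}

# Apply a subset to the window [m, X) of `seq` (0-based half-open),
# returning the edited fragment, per-variant local alt spans (0-based nt
# within the fragment), and remapped local positions. All chosen top-level
# spans must lie within [m, X).
.edit_segment <- function(seq, m, X, variants, positions = integer(0)) {
  frag <- substr(seq, m + 1L, X)
  if (is.null(variants) || !nrow(variants)) {
    pos_local <- positions[positions >= m & positions < X] - m
    return(list(nt = frag, spans = NULL, positions = pos_local))
  }
  local <- variants
  top_idx <- is.na(local$parent_id)
  local$start[top_idx] <- local$start[top_idx] - m
  local$end[top_idx] <- local$end[top_idx] - m
  res <- apply_variants_to_sequence(frag, local,
                                    positions = positions[positions >= m &
                                                            positions < X] - m)
  # recompute realized alt spans in ascending order for annotation
  top <- local[top_idx, , drop = FALSE]
  spans <- NULL
  if (nrow(top)) {
    alt_real <- vapply(seq_len(nrow(top)), function(i) {
      nested <- local[!top_idx & local$parent_id == top$variant_id[i], ,
                      drop = FALSE]
      .realize_alt(top$alt[i], nested)
    }, character(1))
    asc <- order(top$start, top$end, method = "radix")
    shift <- 0L
    rows <- list()
    for (i in asc) {
      pos <- top$start[i] + shift
      len <- nchar(alt_real[i])
      nested <- local[!top_idx & local$parent_id == top$variant_id[i], ,
                      drop = FALSE]
      ids <- c(top$variant_id[i], nested$variant_id)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = ids,
        nt_start = pos, nt_len = len,
        net = nchar(top$ref[i]) - len,
        stringsAsFactors = FALSE
      )
      shift <- shift + len - (top$end[i] - top$start[i])
    }
    spans <- do.call(rbind, rows)
  }
  list(nt = res$seq, spans = spans, positions = res$positions)
}
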