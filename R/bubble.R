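# Variant bubbles: alignment of overlapping variant nodes between
# connection nodes, codon-boundary adjustment, and the pop-and-collapse
# bound on combinatorial growth.

#' Find the next connection node of a frame chain
#'
#' Starting from a connection node (the frame root qualifies), returns the
#' first reference node downstream that is at least five nucleotides long
#' and is a common re-convergence point of all variant paths (no variant
#' span crosses into it). When no further such node exists the chain's
#' terminal (sink) node is returned.
#'
#' @param tvg A `tvg` with variants applied.
#' @param from_node Node id of the current connection node.
#' @return Node id of the next connection node.
#' @export
find_next_connection_node <- function(tvg, from_node) {
  from <- .tvg_get(tvg, from_node)
  f <- from$frame
  refs <- Filter(function(n) {
    n$kind == "ref" && n$frame == f && is.na(n$subgraph_id) &&
      n$start >= from$end
  }, tvg$env$nodes)
  alts <- Filter(function(n) n$kind == "alt" && n$frame == f,
                 tvg$env$nodes)
  aspan <- if (length(alts)) {
    cbind(vapply(alts, `[[`, integer(1), "start"),
          vapply(alts, `[[`, integer(1), "end"))
  } else matrix(integer(0), 0, 2)
  ord <- order(vapply(refs, `[[`, integer(1), "start"))
  refs <- refs[ord]
  sink <- if (length(refs)) refs[[length(refs)]] else from
  for (nd in refs) {
    crossed <- nrow(aspan) > 0 &&
      any(aspan[, 1] < nd$start & aspan[, 2] > nd$start)
    if (crossed) next
    if (nd$end - nd$start >= 5L) return(nd$id)
  }
  sink$id # terminal fallback: the transcript end closes the last bubble
}

# All compatible variant subsets among `items` (top-level rows of a
# variant_table), each expanded with the compatible subsets of its nested
# records. Returns a list of variant_table subsets (possibly zero-row for
# the reference path). `cap` bounds the total number of members.
.enumerate_members <- function(variants, cap = 65536L) {
  top <- variants[is.na(variants$parent_id), , drop = FALSE]
  if (nrow(top)) top <- top[order(top$start, top$end), , drop = FALSE]
  choice_sets <- list()
  for (i in seq_len(nrow(top))) {
    nested <- variants[!is.na(variants$parent_id) &
                         variants$parent_id == top$variant_id[i], ,
                       drop = FALSE]
    opts <- list(NULL) # absent
    nsub <- .compatible_subsets(nested, cap, include_empty = TRUE)
    for (s in nsub) {
      opts[[length(opts) + 1L]] <- rbind(top[i, , drop = FALSE], s)
    }
    choice_sets[[i]] <- opts
  }
  members <- list(variants[0, , drop = FALSE])
  for (i in seq_along(choice_sets)) {
    nxt <- list()
    for (mem in members) {
      for (opt in choice_sets[[i]]) {
        if (is.null(opt)) {
          nxt[[length(nxt) + 1L]] <- mem
          next
        }
        prev_top <- mem[is.na(mem$parent_id), , drop = FALSE]
        ok <- TRUE
        for (j in seq_len(nrow(prev_top))) {
          if (!.spans_compatible(prev_top$start[j], prev_top$end[j],
                                 top$start[i], top$end[i])) {
            ok <- FALSE
            break
          }
        }
        if (ok) nxt[[length(nxt) + 1L]] <- rbind(mem, opt)
        if (length(nxt) > cap) {
          stop("variant bubble exceeds ", cap, " member combinations; ",
               "reduce variant density or raise the cap")
        }
      }
    }
    members <- nxt
  }
  members
}

# Compatible subsets of a (small) set of sibling records, including the
# empty subset... excluded here: returns non-empty subsets only when asked.
.compatible_subsets <- function(df, cap = 65536L, include_empty = FALSE) {
  n <- nrow(df)
  out <- if (include_empty) list(df[0, , drop = FALSE]) else list()
  if (!n) return(out)
  if (n > 20L) stop("too many sibling records to enumerate (", n, ")")
  for (mask in seq_len(2L^n - 1L)) {
    idx <- which(bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L)
    ok <- TRUE
    if (length(idx) > 1L) {
      for (a in seq_len(length(idx) - 1L)) {
        for (b in (a + 1L):length(idx)) {
          if (!.spans_compatible(df$start[idx[a]], df$end[idx[a]],
                                 df$start[idx[b]], df$end[idx[b]])) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
    }
    if (ok) {
      out[[length(out) + 1L]] <- df[idx, , drop = FALSE]
      if (length(out) > cap) stop("subset enumeration exceeded cap ", cap)
    }
  }
  out
}

#' Align the variants between two connection nodes into a bubble
#'
#' Generates all combinations of pairwise-compatible variant choices
#' (the reference path included) between the two anchors, each merged into
#' a single member path; overlapping variants are automatically eliminated
#' because member paths must be internally disjoint.
#'
#' @param tvg A `tvg` with variants applied.
#' @param upstream,downstream Node ids of consecutive connection nodes.
#' @param cap Safety cap on the member count.
#' @return A list of class `variant_bubble` with fields `upstream`,
#'   `downstream`, `frame`, and `members` (list of variant subsets).
#' @export
align_bubble <- function(tvg, upstream, downstream, cap = 65536L) {
  up <- .tvg_get(tvg, upstream)
  down <- .tvg_get(tvg, downstream)
  f <- up$frame
  ids <- unique(unlist(lapply(tvg$env$nodes, function(n) {
    if (n$kind == "alt" && n$frame == f &&
        n$start >= up$end && n$end <= down$start && is.na(n$subgraph_id)) {
      n$variant_id
    } else NULL
  })))
  vt <- tvg$env$variant_registry
  rows <- vt[vt$variant_id %in% ids | (!is.na(vt$parent_id) &
                                         vt$parent_id %in% ids), ,
             drop = FALSE]
  structure(list(
    upstream = upstream, downstream = downstream, frame = f,
    span = c(up$end, down$start),
    members = .enumerate_members(rows, cap = cap)
  ), class = "variant_bubble")
}

#' Adjust bubble member lengths to codon boundaries
#'
#' Realizes each member path as a nucleotide node whose length is a
#' multiple of three, taking whole nucleotides from the commonly connected
#' anchors: the member start is moved into the upstream anchor down to the
#' frame's codon grid, and the member end into the downstream anchor up to
#' the codon grid of the member's outgoing frame (frameshifting members are
#' resolved in their own frame chains, not merged across frames). Anchors
#' shrink accordingly.
#'
#' @param bubble A `variant_bubble`.
#' @param tvg The `tvg` it was aligned on.
#' @return The bubble with `nodes`: one row per member carrying the merged
#'   nucleotide sequence, outgoing frame and variant ids; plus the adjusted
#'   anchor boundaries `anchor_start` (per frame).
#' @export
adjust_to_codon_boundary <- function(bubble, tvg) {
  f <- bubble$frame
  root <- .tvg_get(tvg, tvg$roots[f + 1L])
  r <- root$start # codon grid anchor of this frame
  cs <- bubble$span[1]
  ce <- bubble$span[2]
  m <- if (cs <= r) r else cs - ((cs - r) %% 3L)
  L <- tvg$length
  vt <- tvg$env$variant_registry
  nodes <- lapply(bubble$members, function(mem) {
    top <- mem[is.na(mem$parent_id), , drop = FALSE]
    net <- if (nrow(top)) {
      sum(nchar(top$ref)) - sum(vapply(seq_len(nrow(top)), function(i) {
        nested <- mem[!is.na(mem$parent_id) &
                        mem$parent_id == top$variant_id[i], , drop = FALSE]
        nchar(.realize_alt(top$alt[i], nested))
      }, integer(1)))
    } else 0L
    g <- ((f + net) %% 3L + 3L) %% 3L
    rg <- (r - f + g) # grid anchor of outgoing frame chain
    X <- ce + ((rg - ce) %% 3L)
    terminal <- FALSE
    if (X > L) {
      X <- L
      terminal <- TRUE
    }
    ed <- .edit_segment(tvg$seq, m, X, mem)
    list(nt = ed$nt, frame_out = g, variant_ids = mem$variant_id,
         spans = ed$spans, terminal = terminal, nt_start = m, nt_end = X)
  })
  bubble$nodes <- nodes
  bubble$member_start <- m
  bubble$anchor_start <- vapply(0:2, function(g) {
    rg <- r - f + g
    ce + ((rg - ce) %% 3L)
  }, numeric(1))
  bubble
}

#' Pop-and-collapse: bound bubble growth by sharing identical suffixes
#'
#' Pops the last `x` residues from each member of a bubble and collapses
#' popped suffix nodes that share the same sequence (and outgoing frame)
#' into one shared node whose variant annotations are the union of its
#' contributors. The peptide set generable from the graph is unchanged.
#' Applied only when the member count exceeds `cutoff`.
#'
#' @param members List of member nodes, each a list with at least `aa`
#'   (or `nt`), `frame_out` and `variant_ids`.
#' @param x Number of residues (or nucleotides) to pop.
#' @param cutoff Member-count threshold below which this is a no-op.
#' @param field Which sequence field to operate on (`"aa"` or `"nt"`).
#' @return List with `prefixes` (modified members) and `suffixes` (shared
#'   suffix nodes, each with `members` indices pointing at its
#'   contributors); when not applied, `suffixes` is empty and members are
#'   returned unchanged.
#' @export
pop_and_collapse <- function(members, x = 5L, cutoff = 32L, field = "aa") {
  if (length(members) <= cutoff) {
    return(list(prefixes = members, suffixes = list()))
  }
  lens <- vapply(members, function(m) nchar(m[[field]]), integer(1))
  shortest <- min(lens)
  if (x >= shortest) {
    x <- max(0L, shortest - 1L)
    warning("pop_and_collapse(): x reduced to ", x,
            " (shortest member has ", shortest, " residues)")
  }
  if (x == 0L) return(list(prefixes = members, suffixes = list()))
  keys <- character(length(members))
  suffix_seq <- character(length(members))
  for (i in seq_along(members)) {
    s <- members[[i]][[field]]
    n <- nchar(s)
    suffix_seq[i] <- substr(s, n - x + 1L, n)
    members[[i]][[field]] <- substr(s, 1L, n - x)
    keys[i] <- paste0(members[[i]]$frame_out, "|",
                      if (isTRUE(members[[i]]$terminal)) "T" else "F", "|",
                      suffix_seq[i])
  }
  groups <- split(seq_along(members), keys)
  suffixes <- lapply(groups, function(idx) {
    list(
      seq = suffix_seq[idx[1]],
      frame_out = members[[idx[1]]]$frame_out,
      terminal = isTRUE(members[[idx[1]]]$terminal),
      variant_ids = sort(unique(unlist(lapply(members[idx],
                                              `[[`, "variant_ids")))),
      members = idx
    )
  })
  names(suffixes) <- NULL
  list(prefixes = members, suffixes = suffixes)
}
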