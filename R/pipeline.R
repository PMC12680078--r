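# The graph pipeline: aligned peptide variant graph (PVG), peptide
# cleavage graph (PCG) and stage-and-call peptide emission.
#
# Coordinates here are ORF-rooted: for transcripts with a known ORF the
# caller passes the sequence from the annotated start codon (the 5' UTR
# cannot yield peptides under the edge-case rules); for unknown-ORF
# transcripts the whole sequence is used. Frame chain k covers positions
# congruent to k (mod 3), so a frameshifting member with net length change
# d closes into chain (k + d) mod 3 and downstream codons line up with
# that chain's grid.

.align_down <- function(p, r) {
  if (p <= r) return(r)
  p - ((p - r) %% 3L)
}
.align_up <- function(p, r) p + ((r - p) %% 3L)

# Variant clusters: maximal runs of variant spans not separated by a
# variant-free reference run of >= 5 nt (the connection-node criterion).
.variant_clusters <- function(variants, min_anchor = 5L) {
  top <- variants[is.na(variants$parent_id), , drop = FALSE]
  if (!nrow(top)) return(NULL)
  top <- top[order(top$start, top$end), , drop = FALSE]
  cs <- top$start[1]
  ce <- max(top$end[1], top$start[1]) # zero-width spans
  groups <- list()
  idx <- 1L
  members <- list(top$variant_id[1])
  for (i in seq_len(nrow(top))[-1]) {
    if (top$start[i] - ce >= min_anchor) {
      groups[[idx]] <- list(cs = cs, ce = ce, ids = unlist(members))
      idx <- idx + 1L
      cs <- top$start[i]
      ce <- max(top$end[i], top$start[i])
      members <- list(top$variant_id[i])
    } else {
      ce <- max(ce, top$end[i], top$start[i])
      members[[length(members) + 1L]] <- top$variant_id[i]
    }
  }
  groups[[idx]] <- list(cs = cs, ce = ce, ids = unlist(members))
  groups
}

# Build the aligned, translated peptide variant graph.
#
# seq: ORF-rooted nucleotide sequence; coding: single known ORF at 0.
# variants: variant_table in the same coordinates (already edge-filtered).
# sec: 0-based selenocysteine codon start positions (same coordinates).
.pvg_build <- function(seq, coding, variants, sec = integer(0),
                       pop_cutoff = 32L, pop_x = 5L, cap = 65536L) {
  L <- nchar(seq)
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$next_id <- 1L
  new_node <- function(aa, frame, kind, nt_start = NA_integer_,
                       vdf = NULL) {
    id <- env$next_id
    env$next_id <- id + 1L
    env$nodes[[id]] <- list(id = id, aa = aa, frame = frame, kind = kind,
                            nt_start = nt_start, vdf = vdf,
                            out = integer(0))
    id
  }
  add_edge <- function(from, to) {
    n <- env$nodes[[from]]
    if (!to %in% n$out) {
      n$out <- c(n$out, to)
      env$nodes[[from]] <- n
    }
  }
  shift_any <- nrow(variants) > 0 &&
    any((nchar(variants$ref) - nchar(variants$alt)) %% 3L != 0L)
  frames <- if (!coding) 0:2 else if (shift_any) 0:2 else 0L
  clusters <- .variant_clusters(variants)
  nB <- length(clusters)
  translate_at <- function(a, b) { # [a, b) absolute, frame-aligned at a
    if (b <= a) return("")
    rel_sec <- sec[sec >= a & sec < b] - a
    translate_nt(substr(seq, a + 1L, b), sec_positions = rel_sec,
                 stop_behavior = "keep_stops")
  }
  roots <- rep(NA_integer_, 3L)
  # anchor start/end positions per frame and inter-cluster slot
  for (k in frames) {
    if (k >= L) next
    prev_anchor <- NA_integer_
    for (i in seq_len(nB + 1L)) {
      a_start <- if (i == 1L) k else .align_up(clusters[[i - 1L]]$ce, k)
      a_end <- if (i <= nB) {
        max(a_start, .align_down(clusters[[i]]$cs, k))
      } else L
      if (a_start > L) break
      a_end <- min(a_end, L)
      aid <- new_node(translate_at(a_start, min(a_end, L)), k, "anchor",
                      nt_start = a_start)
      if (i == 1L) roots[k + 1L] <- aid
      env$anchor_ids <- rbind(env$anchor_ids,
                              data.frame(frame = k, slot = i, id = aid,
                                         start = a_start, end = a_end))
      prev_anchor <- aid
    }
  }
  aidx <- env$anchor_ids
  anchor_of <- function(frame, slot) {
    hit <- aidx$id[aidx$frame == frame & aidx$slot == slot]
    if (length(hit)) hit[1] else NA_integer_
  }
  vdf_from_spans <- function(spans, aa_len) {
    if (is.null(spans) || !nrow(spans)) return(NULL)
    aa_start <- spans$nt_start %/% 3L
    aa_end <- pmax(aa_start + 1L, (spans$nt_start + spans$nt_len + 2L) %/% 3L)
    fs <- spans$net %% 3L != 0L
    aa_end[fs] <- aa_len
    keep <- aa_start < aa_len
    if (!any(keep)) return(NULL)
    data.frame(variant_id = spans$variant_id[keep],
               aa_start = aa_start[keep],
               aa_end = pmin(aa_end[keep], aa_len),
               fs = fs[keep], stringsAsFactors = FALSE)
  }
  for (i in seq_len(nB)) {
    cl <- clusters[[i]]
    rows <- variants[variants$variant_id %in% cl$ids |
                       (!is.na(variants$parent_id) &
                          variants$parent_id %in% cl$ids), , drop = FALSE]
    members <- .enumerate_members(rows, cap = cap)
    for (k in frames) {
      if (k >= L || is.na(anchor_of(k, i))) next
      m <- .align_down(cl$cs, k)
      # a cluster reaching into the frame's trimmed 5' offset is edited
      # from the sequence origin and the first k (edited) nt trimmed, so
      # the member stays on this frame's codon grid
      trim <- 0L
      if (cl$cs < k) {
        m <- 0L
        trim <- k
      }
      mem_nodes <- list()
      for (mem in members) {
        top <- mem[is.na(mem$parent_id), , drop = FALSE]
        net <- 0L
        if (nrow(top)) {
          alt_lens <- vapply(seq_len(nrow(top)), function(j) {
            nested <- mem[!is.na(mem$parent_id) &
                            mem$parent_id == top$variant_id[j], ,
                          drop = FALSE]
            nchar(.realize_alt(top$alt[j], nested))
          }, integer(1))
          net <- sum(nchar(top$ref)) - sum(alt_lens)
        }
        g <- ((k + net) %% 3L + 3L) %% 3L
        X <- .align_up(cl$ce, g)
        terminal <- X > L
        if (terminal) X <- L
        ed <- .edit_segment(seq, m, X, mem, positions = sec)
        if (trim > 0L) {
          ed$nt <- substr(ed$nt, trim + 1L, nchar(ed$nt))
          ed$positions <- ed$positions[ed$positions >= trim] - trim
          if (!is.null(ed$spans)) {
            ed$spans$nt_start <- ed$spans$nt_start - trim
            keep <- ed$spans$nt_start + ed$spans$nt_len > 0L
            ed$spans$nt_start <- pmax(ed$spans$nt_start, 0L)
            ed$spans <- ed$spans[keep, , drop = FALSE]
          }
        }
        aa <- translate_nt(ed$nt, sec_positions = ed$positions,
                           stop_behavior = "keep_stops")
        mem_nodes[[length(mem_nodes) + 1L]] <- list(
          aa = aa, frame_out = g, terminal = terminal,
          variant_ids = mem$variant_id,
          vdf = vdf_from_spans(ed$spans, nchar(aa))
        )
      }
      pc <- pop_and_collapse(mem_nodes, x = pop_x, cutoff = pop_cutoff,
                             field = "aa")
      suffix_ids <- integer(length(pc$suffixes))
      for (s in seq_along(pc$suffixes)) {
        sf <- pc$suffixes[[s]]
        svdf <- if (length(sf$variant_ids)) {
          data.frame(variant_id = sf$variant_ids, aa_start = 0L,
                     aa_end = nchar(sf$seq), fs = FALSE,
                     stringsAsFactors = FALSE)
        } else NULL
        suffix_ids[s] <- new_node(sf$seq, k, "suffix", vdf = svdf)
        if (!sf$terminal) {
          nxt <- anchor_of(sf$frame_out, i + 1L)
          if (!is.na(nxt)) add_edge(suffix_ids[s], nxt)
        }
      }
      suffix_of <- integer(length(pc$prefixes))
      if (length(pc$suffixes)) {
        for (s in seq_along(pc$suffixes)) {
          suffix_of[pc$suffixes[[s]]$members] <- suffix_ids[s]
        }
      }
      for (j in seq_along(pc$prefixes)) {
        mn <- pc$prefixes[[j]]
        nid <- new_node(mn$aa, k, "member", vdf = mn$vdf)
        add_edge(anchor_of(k, i), nid)
        if (length(pc$suffixes)) {
          add_edge(nid, suffix_of[j])
        } else if (!mn$terminal) {
          nxt <- anchor_of(mn$frame_out, i + 1L)
          if (!is.na(nxt)) add_edge(nid, nxt)
        }
      }
    }
  }
  structure(list(nodes = env$nodes, roots = roots, frames = frames,
                 coding = coding, seq_len = L,
                 variant_free = nrow(variants) == 0L),
            class = "pvg")
}

#' Translate an aligned transcript variant graph into a peptide graph
#'
#' Convenience wrapper building the aligned, codon-adjusted and translated
#' peptide variant graph for one transcript backbone: variant bubbles are
#' aligned between connection nodes, member lengths adjusted to codon
#' boundaries, hypermutated bubbles reduced by [pop_and_collapse()], and
#' every node translated (stops kept as `*`, selenocysteine honored).
#'
#' @param tx_seq ORF-rooted nucleotide sequence.
#' @param coding Whether the backbone has a known ORF at position 0.
#' @param variants `variant_table` in the same coordinates.
#' @param sec_positions Selenocysteine codon starts (0-based).
#' @param pop_cutoff,pop_x Pop-and-collapse gating and pop size.
#' @return A `pvg` object.
#' @export
translate_graph <- function(tx_seq, coding, variants = empty_variant_table(),
                            sec_positions = integer(0), pop_cutoff = 32L,
                            pop_x = 5L) {
  .pvg_build(tx_seq, coding, variants, sec = sec_positions,
             pop_cutoff = pop_cutoff, pop_x = pop_x)
}

# ---- Peptide cleavage graph -------------------------------------------

# Segments of the PVG delimited by enzymatic cleavage sites: every PCG
# node interior is cleavage-free and every edge is a cleavage site.
# Discovery walks every path from each segment start (node, offset,
# 1-residue upstream context) to the next cut, stop codon or sink.

#' Convert a peptide variant graph into a peptide cleavage graph
#'
#' Every intra-node cleavage site becomes an edge; motifs spanning node
#' boundaries are detected by carrying a one-residue upstream context and a
#' one-residue lookahead across nodes (sufficient for all supported rules,
#' including the trypsin WK/P override). Stop codons terminate segments;
#' residues after a stop start fresh (dead) segments so that downstream
#' novel-ORF methionines remain reachable.
#'
#' @param pvg A `pvg` from [translate_graph()].
#' @param enzyme An [enzyme_spec()] or name.
#' @return A `pcg` object: segments, start-key table and liveness
#'   bookkeeping used by [stage_and_call()] / [extend_miscleavages()].
#' @export
to_cleavage_graph <- function(pvg, enzyme = "trypsin") {
  enzyme <- enzyme_spec(enzyme)
  nodes <- pvg$nodes
  segs <- list()
  key_tab <- new.env(parent = emptyenv()) # key string -> key index
  keys <- list()                          # index -> list(node, off, ctx, root)
  queue <- list()
  key_index <- function(node, off, ctx, root = FALSE) {
    ks <- paste(node, off, ctx, sep = "|")
    idx <- key_tab[[ks]]
    if (is.null(idx)) {
      idx <- length(keys) + 1L
      keys[[idx]] <<- list(node = node, off = off, ctx = ctx, root = root)
      key_tab[[ks]] <- idx
      queue[[length(queue) + 1L]] <<- idx
    }
    idx
  }
  root_keys <- integer(0)
  root_frames <- if (pvg$coding) 0L else pvg$frames
  for (k in root_frames) {
    rid <- pvg$roots[k + 1L]
    if (!is.na(rid)) {
      root_keys <- c(root_keys, key_index(rid, 0L, "", root = TRUE))
    }
  }
  # dead restart after a stop codon: the next residue position along every
  # forward path begins a fresh (not-in-ORF) segment, so downstream
  # novel-ORF methionines stay reachable
  queue_restart <- function(node_id, off) {
    nd <- nodes[[node_id]]
    if (off < nchar(nd$aa)) {
      key_index(node_id, off, "")
    } else {
      for (succ in nd$out) queue_restart(succ, 0L)
    }
  }
  # walk all paths from a start key to cuts/stops/sinks
  walk <- function(key_idx) {
    key <- keys[[key_idx]]
    results <- list()
    rec <- function(node_id, off, acc, prev2, prev1, vrows, nt0) {
      nd <- nodes[[node_id]]
      aa <- nd$aa
      n <- nchar(aa)
      while (TRUE) {
        if (off >= n) {
          if (!length(nd$out)) {
            results[[length(results) + 1L]] <<- list(
              aa = acc, terminal = "sink", succ = NA_integer_,
              vrows = vrows, nt0 = nt0)
            return(invisible(NULL))
          }
          for (succ in nd$out) {
            rec(succ, 0L, acc, prev2, prev1, vrows, nt0)
          }
          return(invisible(NULL))
        }
        r <- substr(aa, off + 1L, off + 1L)
        if (r == "*") {
          results[[length(results) + 1L]] <<- list(
            aa = acc, terminal = "stop", succ = NA_integer_,
            vrows = vrows, nt0 = nt0)
          if (!pvg$coding) queue_restart(node_id, off + 1L)
          return(invisible(NULL))
        }
        if (nzchar(prev1) && .is_cut_site(enzyme, prev2, prev1, r)) {
          succ_key <- key_index(node_id, off, prev1)
          results[[length(results) + 1L]] <<- list(
            aa = acc, terminal = "cut", succ = succ_key,
            vrows = vrows, nt0 = nt0)
          return(invisible(NULL))
        }
        # append residue r
        t_pos <- nchar(acc) # 0-based position of r within the segment
        if (!is.null(nd$vdf)) {
          hit <- nd$vdf[nd$vdf$aa_start <= off & off < nd$vdf$aa_end, ,
                        drop = FALSE]
          if (nrow(hit)) {
            vrows <- rbind(vrows,
                           data.frame(variant_id = hit$variant_id,
                                      pos = t_pos, fs = hit$fs,
                                      stringsAsFactors = FALSE))
          }
        }
        acc <- paste0(acc, r)
        if (nzchar(prev1)) prev2 <- prev1
        prev1 <- r
        off <- off + 1L
      }
    }
    start_node <- nodes[[key$node]]
    nt0 <- if (!is.na(start_node$nt_start)) {
      start_node$nt_start + 3L * key$off
    } else NA_integer_
    rec(key$node, key$off, "", key$ctx, "", NULL, nt0)
    results
  }
  seg_start <- integer(0)
  processed <- 0L
  while (processed < length(queue)) {
    processed <- processed + 1L
    key_idx <- queue[[processed]]
    for (res in walk(key_idx)) {
      segs[[length(segs) + 1L]] <- c(res, list(start = key_idx))
      seg_start <- c(seg_start, key_idx)
    }
  }
  structure(list(
    segments = segs, keys = keys, seg_start = seg_start,
    root_keys = root_keys, coding = pvg$coding,
    variant_free = pvg$variant_free
  ), class = "pcg")
}

#' @export
print.pcg <- function(x, ...) {
  cat(sprintf("<pcg: %d segment(s), %d start key(s), %s backbone>\n",
              length(x$segments), length(x$keys),
              if (x$coding) "coding" else "noncoding"))
  invisible(x)
}

# Carried frameshift context: for backbones with a known ORF, a peptide
# downstream of a frameshifting variant remains attributable to it even
# when none of its own residues overlap the variant span. Propagated as
# the union of frameshift variant ids over predecessor segments (may
# over-attribute when several frameshift routes converge; sources are
# documentation, sequence calling is unaffected). Noncoding backbones
# reach all frames without variants, so nothing is carried there.
.pcg_carry <- function(pcg) {
  nkey <- length(pcg$keys)
  out <- vector("list", nkey)
  if (!pcg$coding) return(out)
  # process in the same topological order as liveness
  n_seg <- length(pcg$segments)
  indeg <- integer(nkey)
  adj <- vector("list", nkey)
  for (i in seq_len(n_seg)) {
    s <- pcg$segments[[i]]
    if (s$terminal == "cut" && !is.na(s$succ)) {
      adj[[s$start]] <- c(adj[[s$start]], i)
      indeg[s$succ] <- indeg[s$succ] + 1L
    }
  }
  q <- which(indeg == 0L)
  while (length(q)) {
    k <- q[1]
    q <- q[-1]
    for (i in adj[[k]]) {
      s <- pcg$segments[[i]]
      fs <- if (!is.null(s$vrows)) {
        unique(s$vrows$variant_id[s$vrows$fs])
      } else character(0)
      out[[s$succ]] <- unique(c(out[[s$succ]], out[[k]], fs))
      indeg[s$succ] <- indeg[s$succ] - 1L
      if (indeg[s$succ] == 0L) q <- c(q, s$succ)
    }
  }
  out
}

# Liveness (stage): ORF state entering each start key, resolved from all
# predecessors before any peptide is emitted. Value semantics: -Inf = not
# inside any ORF; otherwise the nucleotide position of the most recent
# reachable ORF start (0 when positions are not tracked).
.pcg_stage <- function(pcg, novel_orf = !pcg$coding,
                       orf_start_max_nt = Inf) {
  nkey <- length(pcg$keys)
  live <- rep(-Inf, nkey)
  for (rk in pcg$root_keys) if (pcg$coding) live[rk] <- 0
  # topological order over start keys
  n_seg <- length(pcg$segments)
  indeg <- integer(nkey)
  adj <- vector("list", nkey)
  for (i in seq_len(n_seg)) {
    s <- pcg$segments[[i]]
    if (s$terminal == "cut" && !is.na(s$succ)) {
      adj[[s$start]] <- c(adj[[s$start]], i)
      indeg[s$succ] <- indeg[s$succ] + 1L
    }
  }
  order_keys <- integer(0)
  q <- which(indeg == 0L)
  indeg2 <- indeg
  while (length(q)) {
    k <- q[1]
    q <- q[-1]
    order_keys <- c(order_keys, k)
    for (i in adj[[k]]) {
      succ <- pcg$segments[[i]]$succ
      indeg2[succ] <- indeg2[succ] - 1L
      if (indeg2[succ] == 0L) q <- c(q, succ)
    }
  }
  seg_m <- function(s) { # best (latest) valid ORF start within segment
    if (!novel_orf) return(-Inf)
    ms <- gregexpr("M", s$aa, fixed = TRUE)[[1]]
    if (ms[1] == -1L) return(-Inf)
    if (is.finite(orf_start_max_nt)) {
      if (is.na(s$nt0)) return(-Inf)
      pos_nt <- s$nt0 + 3L * (ms - 1L)
      pos_nt <- pos_nt[pos_nt < orf_start_max_nt]
      if (!length(pos_nt)) return(-Inf)
      max(pos_nt)
    } else 0
  }
  for (k in order_keys) {
    for (i in adj[[k]]) {
      s <- pcg$segments[[i]]
      out_val <- max(live[k], seg_m(s))
      if (out_val > live[s$succ]) live[s$succ] <- out_val
    }
  }
  live
}

#' Stage-and-call: emit zero-miscleavage peptides from a cleavage graph
#'
#' Visits every segment after its predecessors, resolving the ORFs under
#' which it is translated (the known ORF for coding backbones; any
#' methionine in any frame chain for noncoding ones, including start-gain
#' methionines inside variant nodes), then emits each in-ORF segment (or
#' methionine-suffix) as a peptide. Upstream frameshift and cleavage-gain
#' context is inherited through the segment chain.
#'
#' @param pcg A `pcg`.
#' @param params A [call_params()].
#' @return data.frame of peptides with miscleavage count 0.
#' @export
stage_and_call <- function(pcg, params = call_params()) {
  extend_miscleavages(pcg, params, max_mc = 0L)
}

#' Extend peptides across cleavage sites (miscleavages)
#'
#' Emits every peptide spanning at most `max_mc` internal cleavage edges
#' along every downstream path, with variant annotations unioned.
#'
#' @param pcg A `pcg`.
#' @param params A [call_params()].
#' @param max_mc Maximum internal miscleavages (defaults to the params
#'   value).
#' @return data.frame with columns `peptide`, `miscleavages`,
#'   `variant_ids` (`;`-joined, sorted, unique) and `n_variants`.
#' @export
extend_miscleavages <- function(pcg, params = call_params(),
                                max_mc = params$max_miscleavage) {
  novel_orf <- !pcg$coding
  cap_nt <- if (is.null(params$orf_cap_nt)) Inf else params$orf_cap_nt
  start_max <- if (is.null(params$orf_start_max_nt)) Inf else
    params$orf_start_max_nt
  live <- .pcg_stage(pcg, novel_orf = novel_orf,
                     orf_start_max_nt = start_max)
  carry <- .pcg_carry(pcg)
  segs <- pcg$segments
  by_key <- split(seq_along(segs), pcg$seg_start)
  succ_of <- function(key) {
    hit <- by_key[[as.character(key)]]
    if (is.null(hit)) integer(0) else hit
  }
  min_len <- params$min_length
  max_len <- params$max_length
  out_pep <- character(0)
  out_mc <- integer(0)
  out_var <- character(0)
  emit <- function(pep, mc, vids) {
    n <- nchar(pep)
    if (n < min_len || n > max_len) return(invisible(NULL))
    if (grepl("X", pep, fixed = TRUE)) return(invisible(NULL))
    out_pep[[length(out_pep) + 1L]] <<- pep
    out_mc[[length(out_mc) + 1L]] <<- mc
    out_var[[length(out_var) + 1L]] <<-
      paste(sort(unique(vids)), collapse = ";")
  }
  for (i in seq_along(segs)) {
    s1 <- segs[[i]]
    n1 <- nchar(s1$aa)
    if (n1 == 0L && s1$terminal == "cut") next
    starts <- integer(0)
    orf_nt <- numeric(0)
    lv <- live[s1$start]
    if (is.finite(lv) || lv == 0) {
      if (lv > -Inf && n1 > 0L) {
        starts <- 0L
        orf_nt <- lv
      }
    }
    if (novel_orf) {
      ms <- gregexpr("M", s1$aa, fixed = TRUE)[[1]]
      if (ms[1] != -1L) {
        for (m in ms) {
          o <- m - 1L
          m_nt <- if (!is.na(s1$nt0)) s1$nt0 + 3L * o else 0
          if (m_nt >= start_max) next
          if (!o %in% starts) {
            starts <- c(starts, o)
            orf_nt <- c(orf_nt, m_nt)
          }
        }
      }
    }
    if (!length(starts)) next
    v1 <- s1$vrows
    carried_in <- carry[[s1$start]]
    for (si in seq_along(starts)) {
      o <- starts[si]
      m_nt <- orf_nt[si]
      base <- substr(s1$aa, o + 1L, n1)
      base_v <- c(carried_in,
                  if (!is.null(v1)) v1$variant_id[v1$pos >= o] else
                    character(0))
      start_nt <- if (!is.na(s1$nt0)) s1$nt0 + 3L * o else NA_real_
      # cap: peptide must lie within 3 circle lengths of its ORF start
      within_cap <- function(total_len) {
        if (!is.finite(cap_nt)) return(TRUE)
        if (is.na(start_nt)) return(TRUE)
        start_nt + 3L * total_len <= m_nt + cap_nt
      }
      chain <- function(seg_idx, acc, acc_v, mc) {
        s <- segs[[seg_idx]]
        # circular backbones have no physical 3' end: peptides must end at
        # a cleavage site or stop codon, never at the linearization sink
        end_ok <- s$terminal != "sink" || !is.finite(cap_nt)
        if (end_ok && within_cap(nchar(acc))) emit(acc, mc, acc_v)
        if (s$terminal != "cut" || mc >= max_mc) return(invisible(NULL))
        if (nchar(acc) >= max_len) return(invisible(NULL))
        for (j in succ_of(s$succ)) {
          s2 <- segs[[j]]
          v2 <- if (!is.null(s2$vrows)) s2$vrows$variant_id else character(0)
          chain(j, paste0(acc, s2$aa), c(acc_v, v2), mc + 1L)
        }
      }
      chain(i, base, base_v, 0L)
    }
  }
  data.frame(peptide = out_pep, miscleavages = out_mc,
             variant_ids = out_var,
             n_variants = ifelse(nzchar(out_var),
                                 lengths(strsplit(out_var, ";")), 0L),
             stringsAsFactors = FALSE)
}

#' Find novel ORF start sites in a cleavage graph
#'
#' Scans every frame chain of a noncoding backbone for methionines —
#' including those inside variant nodes (start-gain mutations). Peptides
#' are attributed to the 5'-most compatible start during calling; this
#' returns the candidate start set.
#'
#' @param pcg A `pcg` built from a noncoding backbone.
#' @return data.frame of candidate starts (segment index, offset).
#' @export
find_novel_orfs <- function(pcg) {
  if (pcg$coding) {
    stop("find_novel_orfs() expects a noncoding backbone")
  }
  rows <- list()
  for (i in seq_along(pcg$segments)) {
    s <- pcg$segments[[i]]
    ms <- gregexpr("M", s$aa, fixed = TRUE)[[1]]
    if (ms[1] == -1L) next
    rows[[length(rows) + 1L]] <- data.frame(
      segment = i, offset = ms - 1L,
      nt_position = if (!is.na(s$nt0)) s$nt0 + 3L * (ms - 1L) else NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(segment = integer(0), offset = integer(0),
                      nt_position = integer(0)))
  }
  do.call(rbind, rows)
}
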