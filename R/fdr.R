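# Target-decoy FDR helpers for downstream database search results.

#' Peptide-level target-decoy FDR
#'
#' `(D + 1) / (T + D)` where `D` and `T` are decoy and target PSM counts.
#' Values above one (possible when targets are scarce) are clipped to one.
#'
#' @param t_count Number of target PSMs.
#' @param d_count Number of decoy PSMs.
#' @return FDR estimate in `[0, 1]`.
#' @export
peptide_fdr <- function(t_count, d_count) {
  stopifnot(t_count >= 0, d_count >= 0)
  if (t_count + d_count == 0) {
    stop("peptide_fdr(): no PSMs (T + D = 0)")
  }
  min(1, (d_count + 1) / (t_count + d_count))
}

#' Post hoc cohort-level FDR cutoff
#'
#' Within each sample (and database tier), the target hit with the highest
#' FDR value under the per-sample threshold defines `FDR_i`; decoy and
#' target hits with FDR values at or below `FDR_i` are tallied, and the
#' cohort-level cutoff is the total decoy count divided by the total
#' target-plus-decoy count across samples. A sample with no sub-threshold
#' target hit contributes nothing.
#'
#' @param hits data.frame with columns `sample`, `is_decoy` (logical) and
#'   `fdr` (per-hit FDR values in `[0, 1]`).
#' @param threshold Per-sample FDR threshold (default 0.01).
#' @return Cohort-level FDR cutoff (0 when no hits qualify).
#' @export
cohort_fdr_cutoff <- function(hits, threshold = 0.01) {
  stopifnot(all(c("sample", "is_decoy", "fdr") %in% names(hits)),
            all(hits$fdr >= 0 & hits$fdr <= 1))
  total_decoy <- 0L
  total_all <- 0L
  for (sm in unique(hits$sample)) {
    h <- hits[hits$sample == sm, , drop = FALSE]
    tgt <- h$fdr[!h$is_decoy & h$fdr < threshold]
    if (!length(tgt)) next
    fdr_i <- max(tgt)
    total_decoy <- total_decoy + sum(h$is_decoy & h$fdr <= fdr_i)
    total_all <- total_all + sum(h$fdr <= fdr_i)
  }
  if (total_all == 0L) return(0)
  total_decoy / total_all
}
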