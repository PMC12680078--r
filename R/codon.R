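# Standard codon table. Stops are '*'; any codon containing a non-ACGT base
# (e.g. N) translates to 'X'.
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  # order: TTT, TTC, TTA, TTG, TCT, ... (first base slowest, third fastest)
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), times = 4L),
                   rep(bases, times = 16L))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  stats::setNames(aas, codons)
})

#' Codon table used for in silico translation
#'
#' Returns the standard codon-to-amino-acid map as a named character vector.
#' Stop codons (TAA, TAG, TGA) map to `"*"`. The selenocysteine override
#' (TGA read as `"U"`) is not part of the table itself; it is applied by
#' [translate_nt()] only at annotated codon positions.
#'
#' @return Named character vector of length 64.
#' @export
codon_table <- function() .codon_table

#' Reverse complement of a nucleotide string
#'
#' @param seq Character scalar over A/C/G/T/N (case-insensitive).
#' @return Reverse-complemented upper-case string.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  x <- chartr("ACGTNacgtn", "TGCANTGCAN", seq)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Translate a nucleotide sequence
#'
#' Codon-wise translation of a spliced transcript (sub)sequence. Translation
#' is frame 0 of `seq`; callers provide pre-trimmed sequences for other
#' frames. A trailing 1-2 nt incomplete codon is dropped. `TGA` codons whose
#' start offset (0-based within `seq`) appears in `sec_positions` are read as
#' selenocysteine (`U`) instead of stop; offsets that are not multiples of
#' three are ignored (the annotated codon is out of frame). Codons containing
#' `N` translate to `X`.
#'
#' @param seq Nucleotide string over A/C/G/T/N.
#' @param sec_positions Integer vector of 0-based codon start offsets within
#'   `seq` at which TGA encodes selenocysteine.
#' @param stop_behavior `"truncate_at_stop"` (default) stops at the first
#'   stop codon and returns the residues before it; `"keep_stops"` returns
#'   the full translation with `*` marking stops (used by the graph stage,
#'   which resolves stops during traversal).
#' @return Amino-acid string (may contain `U`, `X`, and `*` under
#'   `"keep_stops"`).
#' @export
translate_nt <- function(seq, sec_positions = integer(0),
                         stop_behavior = c("truncate_at_stop", "keep_stops")) {
  stopifnot(is.character(seq), length(seq) == 1L)
  stop_behavior <- match.arg(stop_behavior)
  if (grepl("[^ACGTN]", seq)) {
    stop("translate_nt(): sequence contains characters outside A/C/G/T/N")
  }
  n_codon <- nchar(seq) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(.codon_table[codons])
  aa[is.na(aa)] <- "X" # codons containing N
  if (length(sec_positions)) {
    sec_positions <- sec_positions[sec_positions %% 3L == 0L]
    idx <- sec_positions %/% 3L + 1L
    idx <- idx[idx >= 1L & idx <= n_codon]
    hit <- idx[codons[idx] == "TGA"]
    aa[hit] <- "U"
  }
  if (stop_behavior == "truncate_at_stop") {
    first_stop <- match("*", aa)
    if (!is.na(first_stop)) aa <- aa[seq_len(first_stop - 1L)]
  }
  paste(aa, collapse = "")
}
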