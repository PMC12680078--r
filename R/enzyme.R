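# Protease cleavage rules.
#
# Rules are decidable from a window of at most three residues around the
# candidate site (two before, one after). C-side enzymes cut after a residue
# in `cut_after` unless the next residue is in `suppress_next`; trypsin
# additionally overrides the K/P suppression when the K is preceded by W
# (the WK/P override). N-side enzymes cut before a residue in `cut_before`.

.enzyme_specs <- list(
  trypsin = list(
    name = "trypsin", side = "C", cut_after = c("K", "R"),
    suppress_next = "P", wkp_override = TRUE, max_miscleavage = 2L
  ),
  lysc = list(
    name = "lysc", side = "C", cut_after = "K",
    suppress_next = character(0), wkp_override = FALSE, max_miscleavage = 2L
  ),
  lysn = list(
    name = "lysn", side = "N", cut_before = "K", max_miscleavage = 2L
  ),
  argc = list(
    name = "argc", side = "C", cut_after = "R",
    suppress_next = character(0), wkp_override = FALSE, max_miscleavage = 2L
  ),
  gluc = list(
    name = "gluc", side = "C", cut_after = "E",
    suppress_next = character(0), wkp_override = FALSE, max_miscleavage = 3L
  ),
  aspn = list(
    name = "aspn", side = "N", cut_before = "D", max_miscleavage = 3L
  ),
  chymotrypsin = list(
    name = "chymotrypsin", side = "C", cut_after = c("F", "W", "Y"),
    suppress_next = "P", wkp_override = FALSE, max_miscleavage = 4L
  )
)

#' Protease cleavage specification
#'
#' Looks up the cleavage rule set for one of the supported proteases.
#' Trypsin cuts C-terminal of K/R except before proline, with the WK/P
#' override (a K preceded by W cuts even before P). Lys-C, Arg-C and Glu-C
#' cut C-terminal of K, R and E respectively; Lys-N and Asp-N cut N-terminal
#' of K and D; chymotrypsin cuts C-terminal of F/W/Y except before proline.
#' Each enzyme carries the default maximum number of miscleavages used for
#' database generation.
#'
#' @param name One of `"trypsin"`, `"lysc"`, `"lysn"`, `"argc"`, `"gluc"`,
#'   `"aspn"`, `"chymotrypsin"` (case-insensitive).
#' @return A list of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name = "trypsin") {
  if (inherits(name, "enzyme_spec")) return(name)
  key <- tolower(gsub("[^a-z]", "", tolower(name)))
  spec <- .enzyme_specs[[key]]
  if (is.null(spec)) {
    stop("unknown enzyme '", name, "'; supported: ",
         paste(names(.enzyme_specs), collapse = ", "))
  }
  structure(spec, class = "enzyme_spec")
}

#' Table of supported protease rules
#'
#' @return A data.frame with one row per enzyme, for documentation and the
#'   command-line interface.
#' @export
enzyme_rule_table <- function() {
  rows <- lapply(.enzyme_specs, function(e) {
    data.frame(
      enzyme = e$name,
      side = e$side,
      residues = paste(if (e$side == "C") e$cut_after else e$cut_before,
                       collapse = "/"),
      suppressed_before = if (e$side == "C" && length(e$suppress_next)) {
        paste(e$suppress_next, collapse = "/")
      } else "",
      wkp_override = isTRUE(e$wkp_override),
      default_max_miscleavage = e$max_miscleavage,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enzymatic cleavage sites in an amino-acid string
#'
#' Returns the 0-based positions *between* residues at which the enzyme
#' cuts: a site `p` means the bond between residues `p` and `p + 1`
#' (1-based) is cleaved. Exceptions (proline suppression, WK/P override)
#' are applied. Residues `U` (selenocysteine) and `X` are treated as
#' non-cut, non-suppressing residues.
#'
#' @param aa_seq Amino-acid string.
#' @param enzyme An [enzyme_spec()] or enzyme name.
#' @return Integer vector of 0-based cut positions (possibly empty).
#' @export
cleavage_sites <- function(aa_seq, enzyme = "trypsin") {
  enzyme <- enzyme_spec(enzyme)
  n <- nchar(aa_seq)
  if (n < 2L) return(integer(0))
  r <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  if (enzyme$side == "N") {
    # cut before every matching residue except at the N terminus
    return(which(r[-1L] %in% enzyme$cut_before))
  }
  prev <- r[-n]           # residue before candidate bond i (i = 1..n-1)
  nxt <- r[-1L]           # residue after the bond
  cut <- prev %in% enzyme$cut_after
  if (length(enzyme$suppress_next)) {
    suppressed <- cut & nxt %in% enzyme$suppress_next
    if (isTRUE(enzyme$wkp_override)) {
      prev2 <- c("", r[-c(n - 1L, n)]) # residue two before the bond
      suppressed <- suppressed & !(prev == "K" & prev2 == "W")
    }
    cut <- cut & !suppressed
  }
  which(cut)
}

# Decide whether a cut occurs between prev1 and next1 given prev2 context.
# Used by the graph stage where windows cross node boundaries. Empty strings
# denote unavailable context (treated as non-matching).
.is_cut_site <- function(enzyme, prev2, prev1, next1) {
  if (enzyme$side == "N") return(nzchar(next1) && next1 %in% enzyme$cut_before)
  if (!nzchar(prev1) || !(prev1 %in% enzyme$cut_after)) return(FALSE)
  if (length(enzyme$suppress_next) && nzchar(next1) &&
      next1 %in% enzyme$suppress_next) {
    if (isTRUE(enzyme$wkp_override) && prev1 == "K" && identical(prev2, "W")) {
      return(TRUE)
    }
    return(FALSE)
  }
  TRUE
}

#' Exhaustive in silico digestion of a linear protein sequence
#'
#' Digests `aa_seq` with the given enzyme, emitting every peptide with at
#' most `max_mc` internal miscleavages whose length lies within
#' `[min_len, max_len]`. The N-terminal peptide starts at residue one and
#' the C-terminal peptide ends at the final residue; no N-terminal
#' methionine clipping or semi-specific products are generated.
#'
#' @param aa_seq Amino-acid string (no `*`).
#' @param enzyme An [enzyme_spec()] or name.
#' @param max_mc Maximum number of internal miscleavages.
#' @param min_len,max_len Peptide length bounds (residues).
#' @return Character vector of unique peptides.
#' @export
digest_protein <- function(aa_seq, enzyme = "trypsin", max_mc = 2L,
                           min_len = 7L, max_len = 25L) {
  n <- nchar(aa_seq)
  if (n == 0L) return(character(0))
  sites <- cleavage_sites(aa_seq, enzyme)
  bounds <- c(0L, sites, n)
  k <- length(bounds)
  out <- character(0)
  for (i in seq_len(k - 1L)) {
    jmax <- min(k, i + 1L + max_mc)
    for (j in (i + 1L):jmax) {
      len <- bounds[j] - bounds[i]
      if (len > max_len) break
      if (len >= min_len) {
        out <- c(out, substr(aa_seq, bounds[i] + 1L, bounds[j]))
      }
    }
  }
  unique(out)
}
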