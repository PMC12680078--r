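# Gene-centric variant records and the GVF text format.
#
# Variants are carried as a data.frame with one row per (variant,
# transcript): transcript-space coordinates (0-based half-open span of the
# replaced reference bases), reference and alternative sequences, a type
# tag and a source tag. Nested variants (small variants inside the inserted
# sequence of an alternative-splicing event) carry the parent's variant_id
# in `parent_id`, with `start`/`end` then interpreted as offsets within the
# parent's alt sequence.

.variant_types <- c("SNV", "INSERTION", "DELETION", "SUBSTITUTION",
                    "RNA_EDITING", "ALT_SPLICE_SE", "ALT_SPLICE_RI",
                    "ALT_SPLICE_A3SS", "ALT_SPLICE_A5SS", "ALT_SPLICE_MXE",
                    "FUSION", "CIRC_RNA")
.variant_sources <- c("gSNP", "gIndel", "sSNV", "sIndel", "RNAEditing",
                      "AltSplice", "Fusion", "circRNA")

#' Construct a table of gene-centric variant records
#'
#' @param variant_id Stable record identifiers.
#' @param gene_id,tx_id Gene and affected transcript identifiers.
#' @param start,end 0-based half-open transcript coordinates of the replaced
#'   reference span (`end - start == nchar(ref)`).
#' @param ref,alt Reference and alternative nucleotide sequences (either may
#'   be empty, not both).
#' @param type Variant type tag (see Details).
#' @param source Source tag (`gSNP`, `gIndel`, `sSNV`, `sIndel`,
#'   `RNAEditing`, `AltSplice`, `Fusion`, `circRNA`).
#' @param parent_id Optional parent `variant_id` for nested records.
#' @param consequence Optional annotation consequence string (e.g. from
#'   upstream VEP annotation), used by edge-case filtering.
#' @return A `data.frame` of class `variant_table`.
#' @details Supported types: `SNV`, `INSERTION`, `DELETION`, `SUBSTITUTION`,
#'   `RNA_EDITING`, `ALT_SPLICE_SE`/`RI`/`A3SS`/`A5SS`/`MXE`, `FUSION`,
#'   `CIRC_RNA`.
#' @export
variant_table <- function(variant_id, gene_id, tx_id, start, end, ref, alt,
                          type, source, parent_id = NA_character_,
                          consequence = NA_character_) {
  df <- data.frame(
    variant_id = as.character(variant_id),
    gene_id = as.character(gene_id),
    tx_id = as.character(tx_id),
    start = as.integer(start),
    end = as.integer(end),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    type = as.character(type),
    source = as.character(source),
    parent_id = as.character(parent_id),
    consequence = as.character(consequence),
    stringsAsFactors = FALSE
  )
  validate_variant_table(df)
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Validate structural invariants of a variant table
#'
#' Checks span length against the reference sequence, the SNV single-base
#' rule, non-empty alleles and known type/source tags.
#'
#' @param df A variant table (data.frame).
#' @return `df`, invisibly; errors describe the first offending record.
#' @export
validate_variant_table <- function(df) {
  if (!nrow(df)) return(invisible(df))
  bad <- which(!df$type %in% .variant_types)
  if (length(bad)) {
    stop("variant ", df$variant_id[bad[1]], ": unknown type tag '",
         df$type[bad[1]], "'")
  }
  bad <- which(!df$source %in% .variant_sources)
  if (length(bad)) {
    stop("variant ", df$variant_id[bad[1]], ": unknown source tag '",
         df$source[bad[1]], "'")
  }
  span <- df$end - df$start
  bad <- which(span != nchar(df$ref))
  if (length(bad)) {
    stop("variant ", df$variant_id[bad[1]],
         ": end - start (", span[bad[1]], ") != nchar(ref) (",
         nchar(df$ref[bad[1]]), ")")
  }
  bad <- which(df$type == "SNV" & (nchar(df$ref) != 1L | nchar(df$alt) != 1L))
  if (length(bad)) {
    stop("variant ", df$variant_id[bad[1]], ": SNV must have 1-nt ref/alt")
  }
  bad <- which(nchar(df$ref) == 0L & nchar(df$alt) == 0L)
  if (length(bad)) {
    stop("variant ", df$variant_id[bad[1]], ": ref and alt both empty")
  }
  invisible(df)
}

#' An empty variant table
#' @return A zero-row `variant_table`.
#' @export
empty_variant_table <- function() {
  variant_table(character(0), character(0), character(0), integer(0),
                integer(0), character(0), character(0), character(0),
                character(0), parent_id = character(0),
                consequence = character(0))
}

#' Check variant records against a transcript sequence
#'
#' Every top-level record's `ref` must match the transcript sequence over
#' `[start, end)`; nested records are checked against their parent's `alt`.
#'
#' @param variants A `variant_table`.
#' @param tx_seq Transcript nucleotide sequence.
#' @return `TRUE`, invisibly; error naming the first mismatching record.
#' @export
validate_variants_against_sequence <- function(variants, tx_seq) {
  if (!nrow(variants)) return(invisible(TRUE))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    target <- if (!is.na(v$parent_id)) {
      p <- variants[variants$variant_id == v$parent_id, ]
      if (nrow(p) != 1L) {
        stop("variant ", v$variant_id, ": parent '", v$parent_id,
             "' not found")
      }
      p$alt
    } else {
      tx_seq
    }
    seen <- substr(target, v$start + 1L, v$end)
    if (!identical(seen, v$ref)) {
      stop("variant ", v$variant_id, ": ref '", v$ref,
           "' does not match sequence '", seen, "' at [", v$start, ", ",
           v$end, ")")
    }
  }
  invisible(TRUE)
}

.gvf_order <- function(df) {
  order(df$gene_id, df$start, df$alt, df$variant_id, method = "radix")
}

#' Write variant records to a GVF file
#'
#' The GVF dialect is tab-separated with VCF-like columns: CHROM carries the
#' gene ID, POS the 1-based transcript start, then ID/REF/ALT/QUAL/FILTER,
#' and an INFO column with `TRANSCRIPT=`, `TYPE=`, `SOURCE=` and optional
#' `PARENT=`/`CONSEQUENCE=` keys. Empty alleles are written as `.`. Records
#' are ordered deterministically by (gene_id, start, alt, variant_id) so a
#' write/read/write round trip is byte-stable.
#'
#' @param variants A `variant_table`.
#' @param path Output file path.
#' @param annotation_version Free-text annotation tag for the header.
#' @return `path`, invisibly.
#' @export
write_gvf <- function(variants, path, annotation_version = "unspecified") {
  header <- c(
    "##fileformat=GVFv1",
    "##source=pepgraph",
    paste0("##annotation=", annotation_version),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  lines <- header
  if (nrow(variants)) {
    df <- variants[.gvf_order(variants), , drop = FALSE]
    info <- paste0(
      "TRANSCRIPT=", df$tx_id,
      ";TYPE=", df$type,
      ";SOURCE=", df$source,
      ifelse(is.na(df$parent_id), "", paste0(";PARENT=", df$parent_id)),
      ifelse(is.na(df$consequence), "",
             paste0(";CONSEQUENCE=", df$consequence))
    )
    body <- paste(df$gene_id, df$start + 1L, df$variant_id,
                  ifelse(nchar(df$ref) == 0L, ".", df$ref),
                  ifelse(nchar(df$alt) == 0L, ".", df$alt),
                  ".", ".", info, sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

.gvf_info_get <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

#' Read variant records from a GVF file
#'
#' @param path GVF file written by [write_gvf()].
#' @return A `variant_table`.
#' @export
read_gvf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(empty_variant_table())
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 8L)) {
    bad <- which(nf != 8L)[1]
    stop("malformed GVF line ", which(!startsWith(lines, "#"))[bad],
         ": expected 8 tab-separated columns, found ", nf[bad])
  }
  m <- do.call(rbind, fields)
  info <- m[, 8]
  df <- variant_table(
    variant_id = m[, 3],
    gene_id = m[, 1],
    tx_id = .gvf_info_get(info, "TRANSCRIPT"),
    start = as.integer(m[, 2]) - 1L,
    end = as.integer(m[, 2]) - 1L +
      ifelse(m[, 4] == ".", 0L, nchar(m[, 4])),
    ref = ifelse(m[, 4] == ".", "", m[, 4]),
    alt = ifelse(m[, 5] == ".", "", m[, 5]),
    type = .gvf_info_get(info, "TYPE"),
    source = .gvf_info_get(info, "SOURCE"),
    parent_id = .gvf_info_get(info, "PARENT"),
    consequence = .gvf_info_get(info, "CONSEQUENCE")
  )
  df
}
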