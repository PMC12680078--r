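# Reference model: genome assembly, transcript annotation, coordinate maps.
#
# Internal convention: all coordinates are 0-based half-open. GTF input
# (1-based inclusive) is converted on ingestion. Transcript coordinates are
# in spliced-transcript space, 5'->3' on the transcript's own strand.

#' Load a genome assembly from FASTA
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A `genome_assembly`: named character vector of upper-cased
#'   chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  structure(out, class = "genome_assembly")
}

#' Construct a genome assembly from in-memory sequences
#'
#' @param ... Named nucleotide strings (chromosome name = sequence).
#' @return A `genome_assembly`.
#' @export
genome_assembly <- function(...) {
  x <- c(...)
  stopifnot(is.character(x), !is.null(names(x)), all(nzchar(names(x))))
  structure(toupper(x), class = "genome_assembly")
}

#' Extract a genomic subsequence
#'
#' @param genome A `genome_assembly`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Nucleotide string of length `end - start`.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' not present in the assembly")
  }
  n <- nchar(genome[[chrom]])
  if (start < 0L || end > n || start > end) {
    stop("interval [", start, ", ", end, ") out of bounds for '", chrom,
         "' (length ", n, ")")
  }
  substr(genome[[chrom]], start + 1L, end)
}

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (or data.frame) of 0-based half-open
#'   genomic exon intervals, ascending, non-overlapping.
#' @param cds_start_tx,cds_end_tx Optional ORF bounds in transcript
#'   coordinates (0-based half-open, stop codon excluded).
#' @param selenocysteine_tx 0-based transcript coordinates of annotated
#'   selenocysteine (UGA recoding) codon starts.
#' @param tags Character vector of annotation tags
#'   (e.g. `"stop-codon-annotated"`).
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_start_tx = NA_integer_,
                             cds_end_tx = NA_integer_,
                             selenocysteine_tx = integer(0),
                             tags = character(0)) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1L,
            all(exons[, "end"] > exons[, "start"]))
  if (nrow(exons) > 1L) {
    ord <- order(exons[, "start"])
    exons <- exons[ord, , drop = FALSE]
    if (any(exons[-1L, "start"] < exons[-nrow(exons), "end"])) {
      stop("transcript ", transcript_id, ": overlapping exons")
    }
  }
  len <- sum(exons[, "end"] - exons[, "start"])
  is_coding <- !is.na(cds_start_tx) && !is.na(cds_end_tx)
  if (is_coding && !(cds_start_tx < cds_end_tx && cds_end_tx <= len)) {
    stop("transcript ", transcript_id, ": invalid CDS bounds [",
         cds_start_tx, ", ", cds_end_tx, ") for length ", len)
  }
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, exons = exons, length = len,
    cds_start_tx = as.integer(cds_start_tx),
    cds_end_tx = as.integer(cds_end_tx),
    is_coding = is_coding,
    selenocysteine_tx = as.integer(selenocysteine_tx),
    tags = tags
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s%s, %d exon(s), %d nt%s>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$length,
              if (x$is_coding) {
                sprintf(", CDS [%d, %d)", x$cds_start_tx, x$cds_end_tx)
              } else ", noncoding"))
  invisible(x)
}

#' Map a transcript coordinate to a genomic coordinate
#'
#' @param tx A `transcript_model`.
#' @param pos 0-based transcript coordinate(s).
#' @return 0-based genomic coordinate(s) of the same base.
#' @export
tx_to_genomic <- function(tx, pos) {
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= tx$length)) {
    stop("transcript coordinate out of range [0, ", tx$length, ")")
  }
  widths <- tx$exons[, "end"] - tx$exons[, "start"]
  if (tx$strand == "-") {
    widths <- rev(widths)
  }
  offs <- cumsum(c(0L, widths))[seq_along(widths)]
  idx <- findInterval(pos, offs)
  within <- pos - offs[idx]
  if (tx$strand == "+") {
    unname(tx$exons[idx, "start"] + within)
  } else {
    n <- nrow(tx$exons)
    rev_idx <- n + 1L - idx
    unname(tx$exons[rev_idx, "end"] - 1L - within)
  }
}

#' Map a genomic coordinate to a transcript coordinate
#'
#' @param tx A `transcript_model`.
#' @param gpos 0-based genomic coordinate(s).
#' @return 0-based transcript coordinate(s); `NA` where the position does
#'   not fall in an exon.
#' @export
genomic_to_tx <- function(tx, gpos) {
  gpos <- as.integer(gpos)
  widths <- tx$exons[, "end"] - tx$exons[, "start"]
  starts_tx_plus <- cumsum(c(0L, widths))[seq_along(widths)] # + strand
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_along(gpos)) {
    g <- gpos[i]
    hit <- which(tx$exons[, "start"] <= g & g < tx$exons[, "end"])
    if (length(hit) != 1L) next
    if (tx$strand == "+") {
      out[i] <- starts_tx_plus[hit] + (g - tx$exons[hit, "start"])
    } else {
      n <- nrow(tx$exons)
      upstream <- if (hit < n) sum(widths[(hit + 1L):n]) else 0L
      out[i] <- upstream + (tx$exons[hit, "end"] - 1L - g)
    }
  }
  out
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences 5' to 3' on the transcript strand
#' (reverse-complemented for `-` strand transcripts).
#'
#' @param genome A `genome_assembly`.
#' @param tx A `transcript_model` (or anything with `chrom`, `strand`,
#'   `exons`).
#' @return Nucleotide string.
#' @export
transcript_sequence <- function(genome, tx) {
  if (nrow(tx$exons) == 0L) return("")
  parts <- vapply(seq_len(nrow(tx$exons)), function(i) {
    genome_subseq(genome, tx$chrom, tx$exons[i, "start"], tx$exons[i, "end"])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") reverse_complement(s) else s
}

#' Load transcript models from a GTF annotation
#'
#' Accepts GENCODE and Ensembl GTF dialects; only `transcript`, `exon`,
#' `CDS`, `stop_codon` and `Selenocysteine` features are consumed. CDS
#' features are converted to transcript coordinates; the annotated stop
#' codon is excluded from the ORF bounds (translation discovers stops from
#' sequence). Transcripts whose CDS falls outside their exons are rejected
#' with a diagnostic.
#'
#' @param gtf_source Path to a GTF file, or a character scalar containing
#'   GTF text (detected by embedded newlines).
#' @return Named list of [transcript_model()] objects.
#' @export
load_annotation <- function(gtf_source) {
  path <- gtf_source
  if (length(gtf_source) == 1L && grepl("[\t\n]", gtf_source)) {
    path <- tempfile(fileext = ".gtf")
    writeLines(gtf_source, path)
    on.exit(unlink(path))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  keep <- type %in% c("transcript", "exon", "CDS", "stop_codon",
                      "Selenocysteine")
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  tx_id <- as.character(meta$transcript_id)
  if (is.null(meta$transcript_id) || anyNA(tx_id) || any(!nzchar(tx_id))) {
    bad <- which(is.na(tx_id) | !nzchar(tx_id))[1]
    stop("GTF parse error: feature #", bad, " (", type[bad],
         ") lacks a transcript_id attribute")
  }
  gene_id <- if (!is.null(meta$gene_id)) as.character(meta$gene_id) else tx_id
  start0 <- GenomicRanges::start(gr) - 1L # to 0-based half-open
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))

  out <- list()
  for (id in unique(tx_id)) {
    rows <- which(tx_id == id)
    ex <- rows[type[rows] == "exon"]
    if (!length(ex)) next
    exons <- cbind(start = start0[ex], end = end0[ex])
    exons <- exons[order(exons[, "start"]), , drop = FALSE]
    st <- strand[rows[1]]
    tx <- transcript_model(
      transcript_id = id, gene_id = gene_id[rows[1]],
      chrom = chrom[rows[1]], strand = st, exons = exons,
      tags = if (any(type[rows] == "stop_codon")) "stop-codon-annotated"
             else character(0)
    )
    cds_rows <- rows[type[rows] == "CDS"]
    if (length(cds_rows)) {
      cds_pos <- unlist(lapply(cds_rows, function(r) start0[r]:(end0[r] - 1L)))
      tx_pos <- genomic_to_tx(tx, cds_pos)
      if (anyNA(tx_pos)) {
        warning("transcript ", id, ": CDS outside annotated exons; ",
                "model rejected")
        next
      }
      tx <- transcript_model(
        transcript_id = id, gene_id = tx$gene_id, chrom = tx$chrom,
        strand = st, exons = exons,
        cds_start_tx = min(tx_pos), cds_end_tx = max(tx_pos) + 1L,
        tags = tx$tags
      )
    }
    sec_rows <- rows[type[rows] == "Selenocysteine"]
    if (length(sec_rows)) {
      sec_g <- vapply(sec_rows, function(r) {
        if (st == "+") start0[r] else end0[r] - 1L
      }, integer(1))
      sec_tx <- genomic_to_tx(tx, sec_g)
      tx$selenocysteine_tx <- sort(sec_tx[!is.na(sec_tx)])
    }
    out[[id]] <- tx
  }
  out
}

#' Load a canonical proteome from FASTA
#'
#' @param path FASTA file of protein sequences.
#' @return Named character vector of upper-cased amino-acid sequences
#'   (trailing `*` stripped).
#' @export
read_proteome_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(seqs))
  out <- sub("\\*$", "", out)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}
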