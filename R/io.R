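#' Read a transcript FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that enforces unique,
#' non-empty identifiers (the first whitespace-delimited token of each header).
#'
#' @param path Path to a FASTA file of nucleotide sequences.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_transcript_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (length(x) && anyDuplicated(names(x)))
    stop("duplicate transcript IDs in ", path)
  x
}

#' Read a protein FASTA
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A named [Biostrings::AAStringSet].
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#'
#' @param x A named character vector or XStringSet.
#' @param path Output path.
#' @param type `"DNA"` or `"AA"`, used when `x` is a character vector.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (is.character(x)) {
    x <- if (type == "DNA") Biostrings::DNAStringSet(x)
         else Biostrings::AAStringSet(x)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read BLAST tabular output (outfmt-6-like, 12 columns)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore.  Only the columns the pipeline consumes are
#' renamed; the rest are kept.
#'
#' @param path Path to a 12-column tab-separated file without header.
#' @return A data frame with columns `bait_id`, `prey_id`, `identity`
#'   (percent), `ML` (alignment length, aa), `evalue`, `bitscore` plus the
#'   remaining raw columns.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "")
  if (ncol(x) < 12L)
    stop("expected >= 12 tab-separated columns in ", path,
         ", found ", ncol(x))
  names(x)[1:12] <- cols
  data.frame(bait_id = as.character(x$qseqid),
             prey_id = as.character(x$sseqid),
             identity = as.numeric(x$pident),
             ML = as.integer(x$length),
             evalue = as.numeric(x$evalue),
             bitscore = as.numeric(x$bitscore),
             stringsAsFactors = FALSE)
}

#' Write a tab-separated table
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "")
}

#' Write alignment records as a headerful SAM file
#'
#' Emits an `@HD` line, one `@SQ` line per reference, and one alignment line
#' per record.  Unmapped records (flag bit 0x4) are written with `*`
#' reference and position 0, as the format requires.
#'
#' @param records Data frame with columns `qname`, `flag`, `rname`, `pos`
#'   (1-based leftmost position), `seq`.  Optional column `mapq`.
#' @param lengths Named integer vector of reference sequence lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lengths),
                     as.integer(lengths)), con)
  if (nrow(records)) {
    unmapped <- bitwAnd(records$flag, 4L) != 0L
    rname <- ifelse(unmapped, "*", records$rname)
    pos <- ifelse(unmapped, 0L, as.integer(records$pos))
    cigar <- ifelse(unmapped, "*", paste0(nchar(records$seq), "M"))
    mapq <- if ("mapq" %in% names(records)) records$mapq
            else ifelse(unmapped, 0L, 255L)
    writeLines(paste(records$qname, records$flag, rname, pos, mapq, cigar,
                     "*", 0L, 0L, records$seq,
                     strrep("I", nchar(records$seq)), sep = "\t"), con)
  }
  invisible(path)
}
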