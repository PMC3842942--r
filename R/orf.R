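# Six-frame ORF prediction.
#
# Conventions used throughout the package:
#   * coordinates are 0-based, half-open, on the forward strand of the
#     input transcript;
#   * an ORF runs from an ATG to the first in-frame stop (full-length;
#     the stop codon is inside the nt span but excluded from the protein)
#     or to the end of the sequence (fragment);
#   * codons containing N translate to 'X'; 'X' never counts as a match
#     downstream.

.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  tab <- as.character(gc)
  names(tab) <- names(gc)
  tab
})

.translate_codons <- function(codons) {
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  aa
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.check_nt <- function(seq, id) {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    stop("transcript ", id, ": invalid character '",
         substr(seq, bad, bad), "' at position ", bad)
}

# ORFs on one strand of an already-oriented sequence; coordinates local to
# that orientation, mapped back by the caller.
.orfs_one_strand <- function(s, min_len_aa) {
  L <- nchar(s)
  m <- gregexpr("ATG", s, fixed = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(), aa = character(),
                      full = logical(), stringsAsFactors = FALSE))
  }
  out <- vector("list", length(m))
  for (i in seq_along(m)) {
    p <- m[i]                             # 1-based ATG position
    n_codon <- (L - p + 1L) %/% 3L
    if (n_codon < 1L) next
    codons <- substring(s, p + 3L * (seq_len(n_codon) - 1L),
                        p + 3L * seq_len(n_codon) - 1L)
    aa <- .translate_codons(codons)
    stop_at <- which(aa == "*")[1]
    if (!is.na(stop_at)) {
      naa <- stop_at - 1L
      full <- TRUE
      span <- 3L * stop_at                # includes the stop codon
    } else {
      naa <- n_codon
      full <- FALSE
      span <- 3L * n_codon
    }
    if (naa < min_len_aa) next
    out[[i]] <- data.frame(start = p - 1L, end = p - 1L + span,
                           aa = paste(aa[seq_len(naa)], collapse = ""),
                           full = full, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), aa = character(),
                      full = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Enumerate ORFs in all six reading frames
#'
#' Every ATG on either strand is read codon by codon to the first in-frame
#' stop codon (a full-length product) or, when no stop is reached, to the
#' end of the sequence (a protein fragment).  Products shorter than
#' `min_len_aa` amino acids are dropped; the pipeline default is 40.
#'
#' @param id Transcript identifier.
#' @param seq Nucleotide sequence (characters `ACGTN` only).
#' @param min_len_aa Minimum product length in amino acids (>= 1).
#' @return A data frame with one row per candidate: `transcript_id`,
#'   `candidate_id`, `strand` (`+`/`-`), `frame` (0..2 on the reading
#'   strand), `nt_start`, `nt_end` (0-based half-open on the forward strand
#'   of the input), `aa`, `aa_len`, `is_full_length`.
#' @examples
#' six_frame_orfs("t1", "ATGAAATAA", min_len_aa = 1)
#' @export
six_frame_orfs <- function(id, seq, min_len_aa = 40L) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  if (min_len_aa < 1L) stop("min_len_aa must be >= 1")
  seq <- toupper(seq)
  .check_nt(seq, id)
  L <- nchar(seq)

  fwd <- .orfs_one_strand(seq, min_len_aa)
  rev <- .orfs_one_strand(.revcomp(seq), min_len_aa)

  res <- list()
  if (nrow(fwd)) {
    res[[1]] <- data.frame(transcript_id = id, strand = "+",
                           frame = fwd$start %% 3L,
                           nt_start = fwd$start, nt_end = fwd$end,
                           aa = fwd$aa, full = fwd$full,
                           stringsAsFactors = FALSE)
  }
  if (nrow(rev)) {
    # position p..q on the reverse-complement maps to L-q..L-p forward
    res[[2]] <- data.frame(transcript_id = id, strand = "-",
                           frame = rev$start %% 3L,
                           nt_start = L - rev$end, nt_end = L - rev$start,
                           aa = rev$aa, full = rev$full,
                           stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(transcript_id = character(), candidate_id = character(),
                      strand = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      aa = character(), aa_len = integer(),
                      is_full_length = logical(), stringsAsFactors = FALSE))
  }
  x <- do.call(rbind, res)
  data.frame(transcript_id = x$transcript_id,
             candidate_id = paste(x$transcript_id, x$strand, x$frame,
                                  paste0(x$nt_start, "-", x$nt_end),
                                  ifelse(x$full, "F", "Frag"), sep = "|"),
             strand = x$strand, frame = x$frame,
             nt_start = x$nt_start, nt_end = x$nt_end,
             aa = x$aa, aa_len = nchar(x$aa),
             is_full_length = x$full, stringsAsFactors = FALSE)
}

#' Translate a transcript set into a candidate-protein pool
#'
#' Runs [six_frame_orfs()] over every transcript and deduplicates identical
#' amino-acid sequences within a transcript, keeping the candidate with the
#' longest nucleotide span (ties broken by candidate ID).
#'
#' @param transcripts A named character vector or `DNAStringSet`.
#' @param min_len_aa Minimum product length in amino acids; default 40.
#' @return A candidate data frame as from [six_frame_orfs()], rows grouped
#'   by transcript.
#' @export
translate_set <- function(transcripts, min_len_aa = 40L) {
  if (methods::is(transcripts, "DNAStringSet")) {
    transcripts <- stats::setNames(as.character(transcripts),
                                   names(transcripts))
  }
  if (!length(transcripts)) {
    warning("empty transcript set; returning an empty candidate pool")
    return(six_frame_orfs("x", "ATG", min_len_aa = 1L)[0L, ])
  }
  if (is.null(names(transcripts)) || anyDuplicated(names(transcripts)))
    stop("transcripts must carry unique names")
  pool <- lapply(names(transcripts), function(id) {
    orfs <- six_frame_orfs(id, transcripts[[id]], min_len_aa)
    if (!nrow(orfs)) return(orfs)
    span <- orfs$nt_end - orfs$nt_start
    orfs <- orfs[order(orfs$aa, -span, orfs$candidate_id), ]
    orfs[!duplicated(orfs$aa), ]
  })
  out <- do.call(rbind, pool)
  rownames(out) <- NULL
  out
}
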