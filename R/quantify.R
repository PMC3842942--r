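# RPKM quantification: rpkm = 1e9 * C / (N_total * L), with C the
# primarily-mapped read count, L the transcript length in bp and N_total
# the total number of primarily-mapped reads.

#' RPKM from a per-transcript count table
#'
#' Every transcript in `lengths` gets a record, zero-count ones included
#' (so category-aggregation denominators are stable).
#'
#' @param counts Data frame with columns `transcript_id`, `count`.
#' @param lengths Named numeric vector of transcript lengths (bp).
#' @param n_total Total mapped reads; defaults to `sum(counts$count)`.
#'   May exceed the column sum (multimapping reads excluded upstream).
#' @return Data frame `transcript_id`, `C`, `L`, `rpkm`.
#' @export
rpkm_from_counts <- function(counts, lengths, n_total = sum(counts$count)) {
  missing <- setdiff(counts$transcript_id[counts$count > 0], names(lengths))
  if (length(missing))
    stop("no length for counted transcript ", missing[1])
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  if (n_total <= 0) stop("n_total must be positive")
  C <- stats::setNames(rep(0L, length(lengths)), names(lengths))
  idx <- counts$transcript_id %in% names(C)
  C[counts$transcript_id[idx]] <- counts$count[idx]
  data.frame(transcript_id = names(lengths),
             C = as.integer(unname(C)),
             L = as.numeric(unname(lengths)),
             rpkm = 1e9 * unname(C) / (n_total * as.numeric(unname(lengths))),
             stringsAsFactors = FALSE)
}

#' Summary statistics of an RPKM table
#'
#' @param records Output of [rpkm_from_counts()].
#' @return List: `sum`, `mean`, `max`, `dynamic_range` (max/min over
#'   transcripts with nonzero RPKM; `NA` when fewer than one nonzero).
#' @export
rpkm_summary <- function(records) {
  nz <- records$rpkm[records$rpkm > 0]
  list(sum = sum(records$rpkm),
       mean = mean(records$rpkm),
       max = max(records$rpkm),
       dynamic_range = if (length(nz)) max(nz) / min(nz) else NA_real_)
}

#' RPKM from a SAM file
#'
#' Counts primary mapped alignments only (flag bits 0x4 unmapped and
#' 0x100 secondary excluded); `N_total` is the number of such records.
#' Identical to [rpkm_from_counts()] on the induced count table.
#'
#' @param sam_path Path to a headerful SAM file.
#' @param lengths Named numeric vector of transcript lengths; every
#'   reference seen in the SAM must be present.
#' @return Data frame as from [rpkm_from_counts()].
#' @export
rpkm_from_sam <- function(sam_path, lengths) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam))
  x <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = c("flag", "rname")))[[1]]
  keep <- bitwAnd(x$flag, 4L) == 0L & bitwAnd(x$flag, 256L) == 0L
  rn <- as.character(x$rname[keep])
  unknown <- setdiff(unique(rn), names(lengths))
  if (length(unknown))
    stop("transcript ", unknown[1], " in SAM but absent from lengths")
  tab <- table(rn)
  counts <- data.frame(transcript_id = names(tab),
                       count = as.integer(tab), stringsAsFactors = FALSE)
  rpkm_from_counts(counts, lengths, n_total = sum(keep))
}

#' Integer fold of an RPKM over the dataset mean
#'
#' Floored, matching the reporting style "x-fold higher than the mean"
#' (e.g. 11481.33 over a mean of 78.92 is 145-fold).
#'
#' @param rpkm RPKM value(s).
#' @param mean_rpkm Dataset mean RPKM (> 0).
#' @return Integer fold(s).
#' @export
fold_vs_mean <- function(rpkm, mean_rpkm) {
  if (any(mean_rpkm <= 0)) stop("mean_rpkm must be positive")
  as.integer(floor(rpkm / mean_rpkm))
}

#' Sequencing-depth estimate over the probable transcriptome
#'
#' depth = total_read_bases / (genome_size * transcriptome_fraction),
#' i.e. total read length divided by the probable transcriptome size
#' taken as a fixed fraction of the genome.
#'
#' @param total_read_bases Total sequenced bases (bp).
#' @param genome_size Genome size (bp).
#' @param fraction Transcriptome fraction of the genome, in (0, 1].
#' @return List: `total_read_bases`, `genome_size`,
#'   `transcriptome_fraction`, `depth`.
#' @export
estimate_depth <- function(total_read_bases, genome_size, fraction) {
  if (total_read_bases <= 0 || genome_size <= 0)
    stop("total_read_bases and genome_size must be positive")
  if (fraction <= 0 || fraction > 1)
    stop("transcriptome fraction must lie in (0, 1]")
  list(total_read_bases = total_read_bases, genome_size = genome_size,
       transcriptome_fraction = fraction,
       depth = total_read_bases / (genome_size * fraction))
}
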