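# Homology-hit quality metrics and tiered confidence filtering.
#
# A hit relates a bait (query) protein to a prey (subject) protein and
# carries ML (aligned-region length, aa), BL (bait length), PL (prey
# length), percent identity and an e-value.  ML/BL proxies assembly
# accuracy, ML/PL sequence integrity, identity evolutionary variation.
# Ratios are capped at 1.0: local alignments with gaps can make the
# tabular "length" column exceed either sequence length.

#' Attach quality metrics to raw homology hits
#'
#' @param hits Data frame with columns `bait_id`, `prey_id`, `ML`,
#'   `identity`, `evalue` (e.g. from [read_blast_tab()] or
#'   [homology_search()]).
#' @param bait_lengths,prey_lengths Named numeric vectors of sequence
#'   lengths (aa).
#' @return `hits` with columns `BL`, `PL`, `ml_bl`, `ml_pl` added.
#' @export
compute_hit_metrics <- function(hits, bait_lengths, prey_lengths) {
  bl <- unname(bait_lengths[hits$bait_id])
  pl <- unname(prey_lengths[hits$prey_id])
  if (anyNA(bl))
    stop("missing bait length for ", hits$bait_id[which(is.na(bl))[1]])
  if (anyNA(pl))
    stop("missing prey length for ", hits$prey_id[which(is.na(pl))[1]])
  if (any(bl <= 0) || any(pl <= 0))
    stop("sequence lengths must be positive")
  hits$BL <- bl
  hits$PL <- pl
  hits$ml_bl <- pmin(hits$ML / bl, 1.0)
  hits$ml_pl <- pmin(hits$ML / pl, 1.0)
  hits
}

#' Best hit per bait
#'
#' Lowest e-value wins; ties broken by highest identity, then longest ML.
#'
#' @param hits Data frame of hits.
#' @return One row per `bait_id`.
#' @export
best_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$bait_id, hits$evalue, -hits$identity, -hits$ML)
  hits <- hits[o, ]
  hits[!duplicated(hits$bait_id), ]
}

#' Confidence tiers for hit filtering
#'
#' All thresholds are strict minima (`>`).  The tiers are:
#' `core` (ML/BL > 0.5, ML/PL > 0.5, identity > 30), `high` (both ratios
#' > 0.8, identity > 50), `full_length_unique` (ratios > 0.5, identity
#' > 80) and `est_match_strict` (bait-side coverage ML/BL > 0.8, identity
#' > 95; no prey-side constraint).
#'
#' @return Named list of tiers, each a list with `ml_bl`, `ml_pl`,
#'   `identity` minima (`NA` = unconstrained).
#' @export
confidence_tiers <- function() {
  list(core = list(ml_bl = 0.5, ml_pl = 0.5, identity = 30),
       high = list(ml_bl = 0.8, ml_pl = 0.8, identity = 50),
       full_length_unique = list(ml_bl = 0.5, ml_pl = 0.5, identity = 80),
       est_match_strict = list(ml_bl = 0.8, ml_pl = NA, identity = 95))
}

#' Classify hits against a confidence tier
#'
#' @param hits Data frame with `ml_bl`, `ml_pl`, `identity` columns (see
#'   [compute_hit_metrics()]).
#' @param tier A tier from [confidence_tiers()] or a name thereof.
#' @return Logical vector: `TRUE` iff every constrained metric strictly
#'   exceeds its minimum.
#' @export
classify_hits <- function(hits, tier = "core") {
  if (is.character(tier)) tier <- confidence_tiers()[[tier]]
  if (is.null(tier)) stop("unknown confidence tier")
  ok <- rep(TRUE, nrow(hits))
  if (!is.na(tier$ml_bl)) ok <- ok & hits$ml_bl > tier$ml_bl
  if (!is.na(tier$ml_pl)) ok <- ok & hits$ml_pl > tier$ml_pl
  if (!is.na(tier$identity)) ok <- ok & hits$identity > tier$identity
  ok
}

# candidate ordering used by both selection and merging: longest protein
# first, full-length before fragment, then lexicographic candidate ID
.candidate_order <- function(df) {
  order(-df$aa_len, -df$is_full_length, df$candidate_id)
}

#' Select the best translation product for one transcript
#'
#' The longest candidate having any homologue below `e_cut` is chosen;
#' if no candidate has one, the longest overall.  Ties prefer full-length
#' over fragment, then lexicographic candidate ID.
#'
#' @param candidates Candidate data frame (one transcript) as from
#'   [six_frame_orfs()].
#' @param hits Hit data frame whose `bait_id` values are candidate IDs.
#' @param e_cut E-value cutoff, default 1e-5.
#' @return The selected candidate row with `best_prey` and `best_evalue`
#'   columns added (`NA` when selected without a homologue).
#' @export
select_best_candidate <- function(candidates, hits, e_cut = 1e-5) {
  if (!nrow(candidates)) stop("empty candidate set")
  good <- hits[hits$evalue < e_cut & hits$bait_id %in% candidates$candidate_id, ]
  with_hit <- candidates[candidates$candidate_id %in% good$bait_id, ]
  pool <- if (nrow(with_hit)) with_hit else candidates
  sel <- pool[.candidate_order(pool)[1L], ]
  if (nrow(with_hit)) {
    bh <- best_hits(good[good$bait_id == sel$candidate_id, ])
    sel$best_prey <- bh$prey_id
    sel$best_evalue <- bh$evalue
  } else {
    sel$best_prey <- NA_character_
    sel$best_evalue <- NA_real_
  }
  sel
}

#' Select best candidates for every transcript
#'
#' @param candidates Candidate pool from [translate_set()].
#' @param hits Hit data frame (bait = candidate ID).
#' @param e_cut E-value cutoff.
#' @return One selected row per transcript.
#' @export
select_best_candidates <- function(candidates, hits, e_cut = 1e-5) {
  parts <- split(candidates, candidates$transcript_id)
  out <- do.call(rbind, lapply(parts, select_best_candidate,
                               hits = hits, e_cut = e_cut))
  rownames(out) <- NULL
  out[order(out$transcript_id), , drop = FALSE]
}

#' Merge redundant proteins matching the same known protein
#'
#' Proteins sharing a best prey are collapsed to the longest representative
#' (ties: full-length preferred, then lexicographic candidate ID); proteins
#' without a best prey pass through.  The operation is idempotent and
#' invariant under input permutation.
#'
#' @param selected Data frame from [select_best_candidates()] (columns
#'   `candidate_id`, `aa_len`, `is_full_length`, `best_prey` required).
#' @return The merged core dataset with an `n_members` column.
#' @export
merge_redundant <- function(selected) {
  if (!nrow(selected)) {
    selected$n_members <- integer()
    return(selected)
  }
  if (!"n_members" %in% names(selected)) selected$n_members <- 1L
  key <- ifelse(is.na(selected$best_prey),
                paste0("__nohit__", selected$candidate_id),
                selected$best_prey)
  parts <- split(selected, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    rep_row <- g[.candidate_order(g)[1L], ]
    rep_row$n_members <- sum(g$n_members)
    rep_row
  }))
  rownames(out) <- NULL
  out[order(out$candidate_id), , drop = FALSE]
}

#' Core-dataset composition counts
#'
#' @param core Merged core dataset.
#' @return List with `n`, `n_full_length`, `n_fragment`.
#' @export
core_counts <- function(core) {
  list(n = nrow(core),
       n_full_length = sum(core$is_full_length),
       n_fragment = sum(!core$is_full_length))
}

#' Assembly QC against an independent reference set
#'
#' Compares a bait set (e.g. EST sequences from conventional cDNA library
#' sequencing) against the assembly: counts baits matched below `e_cut`,
#' baits passing the strict criterion (bait-side coverage ML/BL > 0.8 and
#' identity > 95 among matched baits), and — over best hits with both
#' ML/BL and ML/PL > 0.5 — how many baits are shorter/longer than their
#' homologues.  Percentages are floored to whole percent.
#'
#' @param hits Metric-annotated hit data frame (bait = reference
#'   sequence).
#' @param n_bait Total number of bait sequences searched (denominator).
#' @param e_cut E-value cutoff, default 1e-5.
#' @param control_hits Optional hit table from a negative control (e.g.
#'   reversed baits); only its matched count is reported.
#' @return List: `n_bait`, `matched`, `matched_pct`, `strict`,
#'   `strict_pct`, `n_compared`, `bait_shorter`, `bait_longer`,
#'   `control_matched` (`NA` when no control given).
#' @export
qc_against_reference <- function(hits, n_bait, e_cut = 1e-5,
                                 control_hits = NULL) {
  if (n_bait <= 0L) stop("empty reference (EST) set")
  good <- hits[hits$evalue < e_cut, , drop = FALSE]
  matched_ids <- unique(good$bait_id)
  matched <- length(matched_ids)
  bh <- best_hits(good)
  strict <- sum(classify_hits(bh, "est_match_strict"))
  cmp <- bh[bh$ml_bl > 0.5 & bh$ml_pl > 0.5, , drop = FALSE]
  ctrl <- NA_integer_
  if (!is.null(control_hits))
    ctrl <- length(unique(control_hits$bait_id[control_hits$evalue < e_cut]))
  list(n_bait = as.integer(n_bait),
       matched = matched,
       matched_pct = floor(100 * matched / n_bait),
       strict = as.integer(strict),
       strict_pct = if (matched > 0) floor(100 * strict / matched) else 0L,
       n_compared = nrow(cmp),
       bait_shorter = sum(cmp$BL < cmp$PL),
       bait_longer = sum(cmp$BL > cmp$PL),
       control_matched = ctrl)
}

# ---- internal BLAST-free homology search -------------------------------

.aa_submat <- local({
  letters <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
               "P","S","T","W","Y","V","X","*")
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m["X", ] <- -1; m[, "X"] <- -1   # X never matches, not even itself
  m
})

.kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Internal homology search (alignment without an external BLAST)
#'
#' A self-contained stand-in for an external sequence search so tests and
#' synthetic runs need no external binary; the tabular reader
#' ([read_blast_tab()]) is the production path for real BLAST output.
#' Pairs sharing at least `min_shared_kmers` length-`k` words are aligned
#' locally (match +1, mismatch -1, linear gap -2, via
#' `Biostrings::pairwiseAlignment`); alignments scoring at least
#' `min_score` become hits.  The reported `evalue` is the monotone
#' surrogate `exp(-score)`, not a Karlin-Altschul statistic.
#'
#' @param baits,preys Named character vectors of protein sequences.
#' @param k Word size for the seeding prefilter.
#' @param min_shared_kmers Minimum shared words to attempt an alignment.
#' @param min_score Minimum local alignment score to report.
#' @return Hit data frame: `bait_id`, `prey_id`, `ML`, `identity`,
#'   `evalue`, `score`.
#' @export
homology_search <- function(baits, preys, k = 5L, min_shared_kmers = 4L,
                            min_score = 20) {
  empty <- data.frame(bait_id = character(), prey_id = character(),
                      ML = integer(), identity = numeric(),
                      evalue = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(baits) || !length(preys)) return(empty)
  # inverted k-mer index over preys, joined against all bait k-mers at
  # once; shared-word counts per (bait, prey) pair via tabulate over a
  # combined integer code, then one batched alignment call
  prey_kmers <- lapply(preys, .kmer_set, k = k)
  idx <- split(rep(seq_along(preys), lengths(prey_kmers)),
               unlist(prey_kmers, use.names = FALSE))
  bait_kmers <- lapply(baits, .kmer_set, k = k)
  bait_i <- rep(seq_along(baits), lengths(bait_kmers))
  hit_lists <- idx[unlist(bait_kmers, use.names = FALSE)]
  nb <- length(baits); np <- length(preys)
  if (nb * np > .Machine$integer.max)
    stop("bait x prey space too large for the seeding prefilter")
  code <- rep(bait_i, lengths(hit_lists)) * np +
    unlist(hit_lists, use.names = FALSE) - np
  counts <- tabulate(code, nb * np)
  pair <- which(counts >= min_shared_kmers)
  if (!length(pair)) return(empty)
  pb <- names(baits)[(pair - 1L) %/% np + 1L]
  pp <- names(preys)[(pair - 1L) %% np + 1L]
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(unname(baits[pb])),
    subject = Biostrings::AAStringSet(unname(preys[pp])),
    type = "local", substitutionMatrix = .aa_submat,
    gapOpening = 0, gapExtension = 2)
  sc <- Biostrings::score(aln)
  keep <- sc >= min_score
  if (!any(keep)) return(empty)
  out <- data.frame(bait_id = pb[keep], prey_id = pp[keep],
                    ML = as.integer(Biostrings::nchar(aln)[keep]),
                    identity = Biostrings::pid(aln, type = "PID1")[keep],
                    evalue = exp(-sc[keep]), score = sc[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
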