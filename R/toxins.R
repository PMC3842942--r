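# Three-strategy toxin discovery: homology to known toxins, domain
# architecture matching, and cysteine-spacing pattern alignment.
#
# The canonical pattern form is the ordered list of inter-cysteine gaps
# (non-cysteine residue counts between consecutive cysteines); a pattern
# with k gaps describes k+1 cysteines.  In the rendered dialect, '#'
# stands for exactly three non-cysteine residues; gaps not divisible by
# three render each remaining residue as 'x'.

#' Extract the cysteine-spacing pattern of a protein
#'
#' Residues before the first and after the last cysteine are ignored.
#' Sequences with fewer than two cysteines yield the empty-pattern
#' sentinel (`gaps` of length zero).
#'
#' @param aa_sequence Amino-acid string.
#' @param id Optional pattern identifier.
#' @return List of class `cys_pattern`: `id`, `gaps` (integer vector),
#'   `n_cys`.
#' @examples
#' extract_cys_pattern("CAAACAAAC")$gaps  # 3 3
#' @export
extract_cys_pattern <- function(aa_sequence, id = NA_character_) {
  stopifnot(nchar(aa_sequence) > 0L)
  pos <- gregexpr("C", aa_sequence, fixed = TRUE)[[1]]
  if (pos[1] == -1L || length(pos) < 2L) {
    out <- list(id = id, gaps = integer(), n_cys = max(0L, length(pos[pos > 0])))
  } else {
    out <- list(id = id, gaps = as.integer(diff(pos) - 1L),
                n_cys = length(pos))
  }
  class(out) <- "cys_pattern"
  out
}

#' Render a cysteine pattern in the '#' dialect
#'
#' '#' denotes exactly three non-cysteine residues; remainders render one
#' 'x' per residue, so arbitrary spacings stay representable.
#'
#' @param pattern A `cys_pattern` or an integer gap vector.
#' @return A character string, e.g. gaps `c(3, 3)` render as `"C#C#C"`.
#' @export
render_cys_pattern <- function(pattern) {
  gaps <- if (inherits(pattern, "cys_pattern")) pattern$gaps else
    as.integer(pattern)
  if (!length(gaps)) return("")
  paste0("C", paste(vapply(gaps, function(g) {
    paste0(strrep("#", g %/% 3L), strrep("x", g %% 3L), "C")
  }, character(1)), collapse = ""))
}

#' Parse a '#'-dialect pattern string back to gaps
#'
#' @param s Pattern string as produced by [render_cys_pattern()].
#' @param id Optional pattern identifier.
#' @return A `cys_pattern`.
#' @export
parse_cys_pattern <- function(s, id = NA_character_) {
  if (!nchar(s)) {
    out <- list(id = id, gaps = integer(), n_cys = 0L)
    class(out) <- "cys_pattern"
    return(out)
  }
  if (grepl("[^C#x]", s)) stop("pattern dialect allows only 'C', '#', 'x'")
  segs <- strsplit(s, "C", fixed = TRUE)[[1]][-1]
  gaps <- vapply(segs, function(g) {
    3L * sum(strsplit(g, "")[[1]] == "#") + sum(strsplit(g, "")[[1]] == "x")
  }, integer(1), USE.NAMES = FALSE)
  out <- list(id = id, gaps = gaps, n_cys = length(gaps) + 1L)
  class(out) <- "cys_pattern"
  out
}

#' Match a cysteine pattern against a candidate protein
#'
#' A match exists at cysteine index j when the candidate's gap
#' subsequence starting there equals the pattern's gaps with each gap
#' differing by at most `tolerance`.  Matching is anchored on the cysteine
#' skeleton only; residue identity between cysteines is ignored.
#'
#' @param candidate_aa Amino-acid string.
#' @param pattern A `cys_pattern` or integer gap vector.
#' @param tolerance Nonnegative integer slack per gap; default 0.
#' @return Integer vector of match start offsets (0-based residue
#'   coordinates of the first matched cysteine); empty when none.
#' @export
match_pattern <- function(candidate_aa, pattern, tolerance = 0L) {
  gaps <- if (inherits(pattern, "cys_pattern")) pattern$gaps else
    as.integer(pattern)
  if (tolerance < 0L) stop("tolerance must be nonnegative")
  if (!length(gaps)) {
    warning("empty cysteine pattern matches nothing")
    return(integer())
  }
  pos <- gregexpr("C", candidate_aa, fixed = TRUE)[[1]]
  if (pos[1] == -1L) return(integer())
  cg <- as.integer(diff(pos) - 1L)
  k <- length(gaps)
  if (length(cg) < k) return(integer())
  hits <- integer()
  for (j in seq_len(length(cg) - k + 1L)) {
    if (all(abs(cg[j:(j + k - 1L)] - gaps) <= tolerance))
      hits <- c(hits, pos[j] - 1L)
  }
  hits
}

#' Compare a domain architecture against reference architectures
#'
#' An architecture hit requires exact ordered equality of domain-ID
#' lists.  Additionally annotates the split pattern of domain runs: runs
#' of same-type consecutive domains separated by a residue gap of at
#' least `gap_min` are reported as e.g. `"14+6"`.
#'
#' @param domains Data frame for one protein: `domain_id`, `start`,
#'   `end`, optional `score`.  Overlapping intervals are resolved by
#'   keeping the higher-score (or first) one.
#' @param reference Data frame with `family` and `architecture`
#'   (comma-separated domain IDs), e.g. from a reference-architecture
#'   table.
#' @param gap_min Minimum inter-domain residue gap that splits a run;
#'   default 50.
#' @return List: `architecture` (comma-separated IDs after overlap
#'   resolution), `family` (matched reference family or `NA`),
#'   `split` (run-length annotation like `"14+6"`).
#' @export
match_domain_architecture <- function(domains, reference, gap_min = 50L) {
  if (!nrow(reference)) stop("reference architecture set is empty")
  if (!nrow(domains))
    return(list(architecture = "", family = NA_character_, split = ""))
  if (!"score" %in% names(domains)) domains$score <- seq(nrow(domains), 1)
  d <- domains[order(domains$start, -domains$score), , drop = FALSE]
  # drop intervals overlapping an already-kept higher-priority one
  keep <- logical(nrow(d))
  last_end <- -Inf
  for (i in seq_len(nrow(d))) {
    if (d$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- d$end[i]
    }
  }
  d <- d[keep, , drop = FALSE]
  arch <- paste(d$domain_id, collapse = ",")
  fam <- reference$family[match(arch, reference$architecture)]
  gapped <- c(FALSE, d$start[-1] - d$end[-nrow(d)] >= gap_min)
  runs <- cumsum(gapped)
  split <- paste(as.integer(table(runs)), collapse = "+")
  list(architecture = arch, family = fam, split = split)
}

#' Call toxin-like proteins by three evidence channels
#'
#' Evidence is the union over: homology (a hit against the known-toxin
#' reference below `e_cut`), domain (exact architecture match to a
#' reference family architecture) and cys_pattern (a pattern-library
#' match at `tolerance`).  Family is taken from the best toxin-homology
#' prey, else from the matched architecture, else `"orphan"`; the
#' functional category comes from `family_map` (missing families map to
#' `"unknown"` with a warning).  No silent curation: every call carries
#' its evidence channels.
#'
#' @param proteins Named character vector of core-dataset proteins.
#' @param toxin_hits Hit data frame against known toxins (bait = protein
#'   ID), or `NULL`.
#' @param toxin_families Named character vector mapping known-toxin
#'   (prey) IDs to families; used by the homology channel.
#' @param domains Domain annotation data frame (`protein_id`,
#'   `domain_id`, `start`, `end`, optional `score`), or `NULL`.
#' @param architectures Reference architecture data frame (`family`,
#'   `architecture`), or `NULL`.
#' @param patterns List of `cys_pattern`s (or gap vectors), or `NULL`.
#' @param family_map Family-to-category map; default
#'   [default_family_categories()].
#' @param rpkm Optional named numeric vector of per-protein RPKMs.
#' @param e_cut Homology e-value cutoff; default 1e-5.
#' @param tolerance Pattern-gap tolerance; default 0.
#' @return Data frame: `protein_id`, `evidence` (comma-joined channels),
#'   `family`, `category`, `rpkm`, sorted by protein ID.
#' @export
call_toxins <- function(proteins, toxin_hits = NULL, toxin_families = NULL,
                        domains = NULL, architectures = NULL,
                        patterns = NULL,
                        family_map = default_family_categories(),
                        rpkm = NULL, e_cut = 1e-5, tolerance = 0L) {
  if (is.null(toxin_hits) && is.null(domains) && is.null(patterns))
    stop("at least one evidence source must be supplied")
  ids <- names(proteins)
  ev_hom <- ev_dom <- ev_cys <- stats::setNames(rep(FALSE, length(ids)), ids)
  fam_hom <- fam_dom <- stats::setNames(rep(NA_character_, length(ids)), ids)

  if (!is.null(toxin_hits) && nrow(toxin_hits)) {
    good <- toxin_hits[toxin_hits$evalue < e_cut &
                         toxin_hits$bait_id %in% ids, , drop = FALSE]
    if (nrow(good)) {
      bh <- best_hits(good)
      ev_hom[bh$bait_id] <- TRUE
      if (!is.null(toxin_families))
        fam_hom[bh$bait_id] <- unname(toxin_families[bh$prey_id])
    }
  }
  if (!is.null(domains) && nrow(domains) && !is.null(architectures)) {
    for (pid in intersect(unique(domains$protein_id), ids)) {
      m <- match_domain_architecture(
        domains[domains$protein_id == pid, , drop = FALSE], architectures)
      if (!is.na(m$family)) {
        ev_dom[pid] <- TRUE
        fam_dom[pid] <- m$family
      }
    }
  }
  if (!is.null(patterns) && length(patterns)) {
    for (pid in ids) {
      for (pat in patterns) {
        gaps <- if (inherits(pat, "cys_pattern")) pat$gaps else pat
        if (!length(gaps)) next
        if (length(match_pattern(proteins[[pid]], gaps, tolerance))) {
          ev_cys[pid] <- TRUE
          break
        }
      }
    }
  }

  called <- ids[ev_hom | ev_dom | ev_cys]
  if (!length(called)) {
    return(data.frame(protein_id = character(), evidence = character(),
                      family = character(), category = character(),
                      rpkm = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(sort(called), function(pid) {
    ev <- c("homology", "domain", "cys_pattern")[
      c(ev_hom[pid], ev_dom[pid], ev_cys[pid])]
    fam <- if (!is.na(fam_hom[pid])) fam_hom[pid]
           else if (!is.na(fam_dom[pid])) fam_dom[pid]
           else "orphan"
    cat <- unname(family_map[fam])
    if (is.na(cat)) {
      warning("family ", fam, " absent from family map; category unknown")
      cat <- "unknown"
    }
    data.frame(protein_id = pid, evidence = paste(ev, collapse = ","),
               family = unname(fam), category = cat,
               rpkm = if (is.null(rpkm)) NA_real_ else
                 unname(rpkm[pid]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-category RPKM sums over a toxin-call table
#'
#' @param calls Output of [call_toxins()].
#' @return Data frame: `category`, `n`, `rpkm_sum`.
#' @export
toxin_category_summary <- function(calls) {
  if (!nrow(calls)) {
    return(data.frame(category = character(), n = integer(),
                      rpkm_sum = numeric(), stringsAsFactors = FALSE))
  }
  s <- tapply(ifelse(is.na(calls$rpkm), 0, calls$rpkm), calls$category, sum)
  k <- tapply(calls$protein_id, calls$category, length)
  data.frame(category = names(s), n = as.integer(k),
             rpkm_sum = as.numeric(s), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Extract a pattern library from a known-toxin set
#'
#' @param toxins Named character vector of known-toxin sequences.
#' @param min_cys Minimum cysteines a sequence needs to contribute a
#'   pattern; default 4.
#' @return Named list of `cys_pattern`s, deduplicated by gap signature,
#'   each carrying its source toxin IDs in `$source_toxin_ids`.
#' @export
extract_pattern_library <- function(toxins, min_cys = 4L) {
  pats <- lapply(names(toxins), function(id)
    extract_cys_pattern(toxins[[id]], id = id))
  pats <- pats[vapply(pats, function(p) p$n_cys >= min_cys, logical(1))]
  if (!length(pats)) return(list())
  sig <- vapply(pats, function(p) paste(p$gaps, collapse = ","), character(1))
  out <- list()
  for (s in unique(sig)) {
    grp <- pats[sig == s]
    p <- grp[[1]]
    p$source_toxin_ids <- vapply(grp, `[[`, character(1), "id")
    p$id <- paste0("PAT_", length(out) + 1L)
    out[[p$id]] <- p
  }
  out
}
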