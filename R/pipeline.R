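# End-to-end orchestration: simulate (optional) -> translate -> homology
# filter -> select/merge -> quantify -> toxin discovery -> enrichment ->
# report.  Every stage reads and writes plain files in the output
# directory, so each is usable standalone and a run can resume from any
# stage; the report file is byte-deterministic for a fixed config + seed.

#' Build and validate a pipeline run configuration
#'
#' @param outdir Output directory for all stage files.
#' @param seed Integer seed used by the simulation stage.
#' @param simulate If `TRUE`, generate the synthetic inputs first;
#'   otherwise the input files must already exist in `outdir` (or be
#'   provided via the `*_path` arguments).
#' @param sim_config A [simulation_config()] used when `simulate = TRUE`.
#' @param transcripts_path,reference_path,ref_meta_path,counts_path,domains_path,architectures_path,pathways_path
#'   Optional explicit input paths; default to the simulation filenames
#'   inside `outdir`.
#' @param blast_tab_path Optional pre-computed BLAST tabular file; when
#'   absent the internal [homology_search()] is used.
#' @param min_len_aa Minimum ORF length (aa); default 40.
#' @param e_cut Homology e-value cutoff; default 1e-5.
#' @param enrichment_cutoff Enrichment significance cutoff; default 0.05.
#' @param pattern_tolerance Cysteine-pattern gap tolerance; default 0.
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, simulate = TRUE,
                       sim_config = simulation_config(seed = seed),
                       transcripts_path = NULL, reference_path = NULL,
                       ref_meta_path = NULL, counts_path = NULL,
                       domains_path = NULL, architectures_path = NULL,
                       pathways_path = NULL, blast_tab_path = NULL,
                       min_len_aa = 40L, e_cut = 1e-5,
                       enrichment_cutoff = 0.05, pattern_tolerance = 0L) {
  if (min_len_aa < 1L) stop("min_len_aa must be >= 1")
  if (e_cut <= 0) stop("e_cut must be positive")
  if (enrichment_cutoff <= 0 || enrichment_cutoff >= 1)
    stop("enrichment_cutoff must lie in (0, 1)")
  if (pattern_tolerance < 0L) stop("pattern_tolerance must be nonnegative")
  p <- function(given, default) if (is.null(given)) file.path(outdir, default)
       else given
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              simulate = isTRUE(simulate), sim_config = sim_config,
              transcripts_path = p(transcripts_path, "transcripts.fasta"),
              reference_path = p(reference_path, "reference.fasta"),
              ref_meta_path = p(ref_meta_path, "reference_meta.tsv"),
              counts_path = p(counts_path, "counts.tsv"),
              domains_path = p(domains_path, "domains.tsv"),
              architectures_path = p(architectures_path,
                                     "ref_architectures.tsv"),
              pathways_path = p(pathways_path, "pathways.tsv"),
              blast_tab_path = blast_tab_path,
              min_len_aa = as.integer(min_len_aa), e_cut = e_cut,
              enrichment_cutoff = enrichment_cutoff,
              pattern_tolerance = as.integer(pattern_tolerance))
  class(cfg) <- "run_config"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

.need <- function(path, stage) {
  if (!file.exists(path))
    stop("stage ", stage, ": required input ", path, " does not exist",
         call. = FALSE)
  path
}

#' Run the simulation stage
#' @param config A [run_config()].
#' @return Written file paths, invisibly.
#' @export
stage_simulate <- function(config) {
  .stage("simulate", {
    sim <- generate_transcriptome(config$sim_config)
    reads <- generate_reads(sim)
    write_simulation(sim, reads, config$outdir)
  })
}

#' Run the translation stage
#' @param config A [run_config()].
#' @return The candidate pool, invisibly; writes `candidates.tsv` and
#'   `candidates.fasta`.
#' @export
stage_translate <- function(config) {
  .need(config$transcripts_path, "translate")
  .stage("translate", {
    tr <- read_transcript_fasta(config$transcripts_path)
    if (!length(tr)) stop("empty transcript FASTA")
    pool <- translate_set(tr, config$min_len_aa)
    write_tsv(pool, file.path(config$outdir, "candidates.tsv"))
    write_fasta(stats::setNames(pool$aa, pool$candidate_id),
                file.path(config$outdir, "candidates.fasta"), "AA")
    invisible(pool)
  })
}

#' Run the homology-search stage
#' @param config A [run_config()].
#' @return Metric-annotated hits, invisibly; writes `hits.tsv`.
#' @export
stage_homology <- function(config) {
  .stage("homology", {
    pool <- read_tsv(.need(file.path(config$outdir, "candidates.tsv"),
                           "homology"))
    refs <- as.character(read_protein_fasta(
      .need(config$reference_path, "homology")))
    hits <- if (!is.null(config$blast_tab_path))
      read_blast_tab(config$blast_tab_path)
    else
      homology_search(stats::setNames(pool$aa, pool$candidate_id), refs)
    hits <- compute_hit_metrics(
      hits, stats::setNames(nchar(pool$aa), pool$candidate_id),
      stats::setNames(nchar(refs), names(refs)))
    write_tsv(hits, file.path(config$outdir, "hits.tsv"))
    invisible(hits)
  })
}

#' Run best-candidate selection and redundancy merge
#' @param config A [run_config()].
#' @return The core dataset, invisibly; writes `core.tsv`.
#' @export
stage_select <- function(config) {
  .stage("select", {
    pool <- read_tsv(.need(file.path(config$outdir, "candidates.tsv"),
                           "select"))
    hits <- read_tsv(.need(file.path(config$outdir, "hits.tsv"), "select"))
    sel <- select_best_candidates(pool, hits, config$e_cut)
    core <- merge_redundant(sel)
    core$protein_id <- paste0("P_", core$transcript_id)
    write_tsv(core, file.path(config$outdir, "core.tsv"))
    invisible(core)
  })
}

#' Run the quantification stage
#' @param config A [run_config()].
#' @return RPKM records, invisibly; writes `rpkm.tsv`.
#' @export
stage_quantify <- function(config) {
  .stage("quantify", {
    tr <- read_transcript_fasta(.need(config$transcripts_path, "quantify"))
    lens <- stats::setNames(Biostrings::width(tr), names(tr))
    counts <- read_tsv(.need(config$counts_path, "quantify"))
    recs <- rpkm_from_counts(counts, lens)
    write_tsv(recs, file.path(config$outdir, "rpkm.tsv"))
    invisible(recs)
  })
}

#' Run the toxin-discovery stage
#' @param config A [run_config()].
#' @return Toxin calls, invisibly; writes `toxins.tsv`.
#' @export
stage_toxins <- function(config) {
  .stage("toxins", {
    core <- read_tsv(.need(file.path(config$outdir, "core.tsv"), "toxins"))
    recs <- read_tsv(.need(file.path(config$outdir, "rpkm.tsv"), "toxins"))
    refs <- as.character(read_protein_fasta(
      .need(config$reference_path, "toxins")))
    meta <- read_tsv(.need(config$ref_meta_path, "toxins"))
    tox_refs <- refs[meta$ref_id[meta$is_toxin]]
    fams <- stats::setNames(meta$family, meta$ref_id)

    proteins <- stats::setNames(core$aa, core$protein_id)
    rpkm <- stats::setNames(recs$rpkm, paste0("P_", recs$transcript_id))
    hits <- homology_search(proteins, tox_refs)
    pats <- extract_pattern_library(tox_refs)
    domains <- if (file.exists(config$domains_path))
      read_tsv(config$domains_path) else NULL
    archs <- if (file.exists(config$architectures_path))
      read_tsv(config$architectures_path) else NULL
    calls <- call_toxins(proteins, toxin_hits = hits,
                         toxin_families = fams, domains = domains,
                         architectures = archs, patterns = pats,
                         rpkm = rpkm, e_cut = config$e_cut,
                         tolerance = config$pattern_tolerance)
    write_tsv(calls, file.path(config$outdir, "toxins.tsv"))
    invisible(calls)
  })
}

#' Run the enrichment stage
#'
#' The gene set under test is the top abundance quartile of core proteins
#' by RPKM.
#'
#' @param config A [run_config()].
#' @return Enrichment results, invisibly; writes `enrichment.tsv`.
#' @export
stage_enrich <- function(config) {
  .stage("enrich", {
    core <- read_tsv(.need(file.path(config$outdir, "core.tsv"), "enrich"))
    recs <- read_tsv(.need(file.path(config$outdir, "rpkm.tsv"), "enrich"))
    map <- read_tsv(.need(config$pathways_path, "enrich"))
    rpkm <- stats::setNames(recs$rpkm, paste0("P_", recs$transcript_id))
    pop <- core$protein_id
    r <- rpkm[pop]
    gene_set <- pop[order(-r, pop)][seq_len(max(1L, length(pop) %/% 4L))]
    res <- enrich_pathways(map, population = pop, gene_set = gene_set,
                           cutoff = config$enrichment_cutoff, rpkm = rpkm)
    write_tsv(res, file.path(config$outdir, "enrichment.tsv"))
    invisible(res)
  })
}

#' Run the whole pipeline
#'
#' Executes all stages in order and writes a deterministic `report.txt`
#' plus a timestamped `run.log`.
#'
#' @param config A [run_config()].
#' @return A list of class `venomtx_report` with per-stage counts and
#'   result tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  logf <- file.path(config$outdir, "run.log")
  cat(sprintf("run started %s\n", format(Sys.time())), file = logf)
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    cat(sprintf("%s: %.2fs\n", stage,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))),
        file = logf, append = TRUE)
    res
  }
  if (config$simulate) tick("simulate", stage_simulate(config))
  pool <- tick("translate", stage_translate(config))
  hits <- tick("homology", stage_homology(config))
  core <- tick("select", stage_select(config))
  recs <- tick("quantify", stage_quantify(config))
  calls <- tick("toxins", stage_toxins(config))
  enr <- tick("enrich", stage_enrich(config))

  tiers <- confidence_tiers()
  bh <- best_hits(hits)
  tier_counts <- vapply(names(tiers), function(t)
    sum(classify_hits(bh, t)), integer(1))
  tr <- read_transcript_fasta(config$transcripts_path)
  summary <- summarize_counts(
    stats::setNames(Biostrings::width(tr), names(tr)),
    tier_counts = tier_counts)
  report <- list(seed = config$seed,
                 n_transcripts = length(tr),
                 n_candidates = nrow(pool),
                 n_hits = nrow(hits),
                 tier_counts = tier_counts,
                 core = core_counts(core),
                 rpkm = rpkm_summary(recs),
                 toxin_calls = calls,
                 toxin_categories = toxin_category_summary(calls),
                 enrichment = enr,
                 summary = summary)
  class(report) <- "venomtx_report"
  .write_report(report, file.path(config$outdir, "report.txt"))
  report
}

.write_report <- function(r, path) {
  fmt <- function(x) formatC(x, format = "g", digits = 10)
  lines <- c(
    "venomtx run report",
    sprintf("seed\t%d", r$seed),
    sprintf("transcripts\t%d", r$n_transcripts),
    sprintf("mean_transcript_length\t%s", fmt(r$summary$mean_length)),
    sprintf("transcripts_gt_2000bp\t%d", r$summary$n_gt_2000),
    sprintf("candidates\t%d", r$n_candidates),
    sprintf("hits\t%d", r$n_hits),
    sprintf("tier_%s\t%d", names(r$tier_counts), r$tier_counts),
    sprintf("core_proteins\t%d", r$core$n),
    sprintf("core_full_length\t%d", r$core$n_full_length),
    sprintf("core_fragments\t%d", r$core$n_fragment),
    sprintf("rpkm_sum\t%s", fmt(r$rpkm$sum)),
    sprintf("rpkm_mean\t%s", fmt(r$rpkm$mean)),
    sprintf("toxin_calls\t%d", nrow(r$toxin_calls)),
    sprintf("toxin_category\t%s\t%d\t%s", r$toxin_categories$category,
            r$toxin_categories$n, fmt(r$toxin_categories$rpkm_sum)),
    sprintf("enriched_pathways\t%d", sum(r$enrichment$significant)),
    sprintf("top_pathway\t%s\t%s", r$enrichment$term_id[1],
            fmt(r$enrichment$p_value[1])))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.venomtx_report <- function(x, ...) {
  cat("venomtx pipeline report\n")
  cat(sprintf("  transcripts: %d  candidates: %d  core proteins: %d\n",
              x$n_transcripts, x$n_candidates, x$core$n))
  cat(sprintf("  toxin calls: %d  enriched pathways: %d\n",
              nrow(x$toxin_calls), sum(x$enrichment$significant)))
  invisible(x)
}

#' Assembly/run summary counts
#'
#' Totals in the style of a sequencing-statistics table: transcript
#' count, mean length, transcripts over 2000 bp, total read bases and any
#' supplied tier survivor counts.
#'
#' @param lengths Named numeric vector of transcript lengths (bp).
#' @param n_reads,read_length Optional read totals; when both are given,
#'   `total_bases = n_reads * read_length` is included.
#' @param tier_counts Optional named integer vector of tier survivors.
#' @return List of summary values.
#' @export
summarize_counts <- function(lengths, n_reads = NULL, read_length = NULL,
                             tier_counts = NULL) {
  out <- list(n_transcripts = length(lengths),
              mean_length = mean(lengths),
              n_gt_2000 = sum(lengths > 2000),
              total_bases = if (!is.null(n_reads) && !is.null(read_length))
                as.numeric(n_reads) * as.numeric(read_length) else NA_real_,
              tier_counts = tier_counts)
  out
}
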