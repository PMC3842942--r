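# Hypergeometric pathway enrichment and per-category RPKM aggregation.

#' Upper-tail hypergeometric probability
#'
#' P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M, n-i) / C(N,n), i.e. the
#' probability of observing at least `m` successes in a sample of `n`
#' drawn without replacement from a population of `N` containing `M`
#' successes.  Computed via `stats::phyper` (log-space safe); the observed
#' count is inside the rejection tail, as the sum's upper limit `m-1`
#' dictates.
#'
#' @param N Population size.
#' @param M Successes in the population.
#' @param n Sample size.
#' @param m Observed successes in the sample.
#' @return P(X >= m), in `[0, 1]`; `m = 0` gives exactly 1.
#' @export
hypergeom_p <- function(N, M, n, m) {
  if (M > N) stop("M exceeds N (successes cannot outnumber the population)")
  if (n > N) stop("n exceeds N (sample cannot outnumber the population)")
  if (m < 0) stop("m must be nonnegative")
  if (m > min(M, n)) stop("m exceeds min(M, n)")
  if (m == 0) return(1)
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment over a pathway map
#'
#' Two parameter mappings are available because prose descriptions and the
#' tail formula cannot always be reconciled under one reading:
#' * `"per_pathway"` (default): for each pathway, `N` = proteins in the
#'   population with any pathway mapping, `M` = the pathway's members in
#'   that population, `n` = the gene set under test (intersected with the
#'   mapped population), `m` = overlap of gene set and pathway.
#' * `"prose"`: `N` = the whole population, `M` = proteins with any
#'   pathway mapping, `n` = the pathway's members in the population,
#'   `m` = mapped members of the pathway (`gene_set` unused).
#'
#' @param pathway_map Data frame with columns `protein_id`, `term_id`.
#' @param population Character vector of protein IDs (the core dataset).
#' @param gene_set Character vector of protein IDs under test (default:
#'   the mapped population, relevant only for `"per_pathway"`).
#' @param cutoff Significance cutoff (strict, P < cutoff); default 0.05.
#' @param mapping Parameter mapping, see above.
#' @param rpkm Optional named numeric vector; adds per-pathway `rpkm_sum`.
#' @param adjust If `TRUE`, adds Benjamini-Hochberg adjusted P values in
#'   `p_adjusted` (significance still uses the raw P, as the default
#'   analysis does).
#' @return Data frame sorted by P: `term_id`, `N`, `M`, `n`, `m`,
#'   `p_value`, `significant`, `rpkm_sum`, optionally `p_adjusted`.
#' @export
enrich_pathways <- function(pathway_map, population, gene_set = NULL,
                            cutoff = 0.05,
                            mapping = c("per_pathway", "prose"),
                            rpkm = NULL, adjust = FALSE) {
  mapping <- match.arg(mapping)
  if (!nrow(pathway_map)) stop("pathway map is empty")
  terms <- sort(unique(pathway_map$term_id))
  pathway_map <- pathway_map[pathway_map$protein_id %in% population, ,
                             drop = FALSE]
  mapped <- unique(pathway_map$protein_id)
  if (is.null(gene_set)) gene_set <- mapped
  gene_set <- intersect(gene_set, mapped)
  members <- split(pathway_map$protein_id, pathway_map$term_id)

  rows <- lapply(terms, function(tm) {
    mem <- unique(members[[tm]])
    if (!length(mem)) {
      warning("pathway ", tm, " has no mapped proteins; P = 1")
      return(data.frame(term_id = tm, N = length(mapped), M = 0L, n = 0L,
                        m = 0L, p_value = 1, stringsAsFactors = FALSE))
    }
    if (mapping == "per_pathway") {
      N <- length(mapped); M <- length(mem)
      n <- length(gene_set); m <- length(intersect(gene_set, mem))
    } else {
      N <- length(unique(population)); M <- length(mapped)
      n <- length(mem); m <- length(intersect(mem, mapped))
    }
    data.frame(term_id = tm, N = N, M = M, n = n, m = m,
               p_value = hypergeom_p(N, M, n, m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < cutoff
  out$rpkm_sum <- NA_real_
  if (!is.null(rpkm)) {
    out$rpkm_sum <- vapply(out$term_id, function(tm) {
      mem <- unique(members[[tm]])
      sum(rpkm[intersect(mem, names(rpkm))])
    }, numeric(1))
  }
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate RPKM by annotation category
#'
#' For each term: the sum of member RPKMs, the member count and the mean.
#' Proteins annotated to several terms contribute fully to each.
#'
#' @param annotations Data frame with columns `protein_id`, `term_id`.
#' @param rpkm Named numeric vector; every annotated protein must be
#'   present (zero allowed).
#' @return Data frame: `term_id`, `rpkm_sum`, `protein_count`,
#'   `rpkm_mean`.
#' @export
aggregate_rpkm_by_category <- function(annotations, rpkm) {
  unknown <- setdiff(unique(annotations$protein_id), names(rpkm))
  if (length(unknown))
    stop("annotation references unknown protein ", unknown[1])
  ann <- unique(annotations[c("protein_id", "term_id")])
  v <- rpkm[ann$protein_id]
  s <- tapply(v, ann$term_id, sum)
  k <- tapply(v, ann$term_id, length)
  data.frame(term_id = names(s),
             rpkm_sum = as.numeric(s),
             protein_count = as.integer(k),
             rpkm_mean = as.numeric(s) / as.integer(k),
             stringsAsFactors = FALSE, row.names = NULL)
}
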