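# Synthetic venom-gland transcriptome with known ground truth.
#
# The generator emulates the input side of a de-novo venom-gland RNA-seq
# study: assembled transcripts carrying one planted principal ORF each
# (both strands), a divergent "known protein" reference database derived
# from the planted translations, a subset of toxin genes carrying defined
# cysteine-spacing scaffolds and domain architectures, pathway membership
# maps, and reads drawn at known power-law abundances.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

# toxin families and their fixed functional categories
.FAMILY_CATEGORY <- c(
  "ANK_superfamily"     = "neurotoxin",
  "SCP"                 = "neurotoxin",
  "lycotoxin"           = "neurotoxin",
  "theriditoxin"        = "assistant",
  "trypsin"             = "protease",
  "ctenitoxin"          = "protease_inhibitor",
  "scorpion_toxin_like" = "unknown",
  "orphan"              = "unknown")

# deterministic domain architecture per family (domain_id list); families
# without a characteristic architecture are absent.
.FAMILY_ARCHITECTURE <- list(
  ANK_superfamily = rep("ANK", 6L),
  SCP             = "SCP",
  lycotoxin       = "toxin_35",
  trypsin         = "trypsin",
  ctenitoxin      = c("TY", "TY"))

#' Default family-to-category map for toxin calls
#'
#' Five functional categories: neurotoxins (ANK superfamily, SCP,
#' lycotoxin), assistant toxins (theriditoxin), proteases (trypsin),
#' protease inhibitors (TY-domain ctenitoxins) and unknown-function toxins
#' (scorpion-toxin-like, orphan).
#'
#' @return Named character vector mapping family to category.
#' @export
default_family_categories <- function() .FAMILY_CATEGORY

#' Build and validate a simulation configuration
#'
#' Defaults describe a desk-scale venom-gland world: 200 transcripts of
#' 300-3000 bp, 20 toxin genes carrying knottin-like cysteine scaffolds,
#' reference proteins at 10% per-site divergence, power-law abundances with
#' exponent 1.75 (so 200 ranks span ~4 orders of magnitude; the real gland
#' spans more than 1e6 across ~34k transcripts), and 5e5 90-bp reads with a
#' 1% per-base substitution error rate.
#'
#' @param seed Integer RNG seed; the whole run is reproducible from it.
#' @param n_transcripts Number of transcripts.
#' @param length_range Two-element bp interval; minimum >= 150 so a 40-aa
#'   ORF fits.
#' @param n_toxin_genes Number of transcripts carrying a planted toxin.
#' @param toxin_scaffolds List of inter-cysteine gap vectors planted into
#'   toxin ORFs.
#' @param divergence Per-site substitution probability in `[0,1]` applied
#'   when deriving "known" reference proteins from planted translations.
#' @param mutate_cys If `FALSE` (default), divergence never creates or
#'   destroys a cysteine, so pattern-recall tests separate signal decay
#'   from matcher bugs.
#' @param abundance_law Power-law exponent over abundance ranks.
#' @param read_length Read length in bp.
#' @param n_reads Number of reads to draw.
#' @param error_rate Per-base substitution error probability.
#' @param n_pathways Number of pathway terms in the membership map.
#' @param pathway_size Proteins per pathway.
#' @param enriched_pathway If `TRUE`, pathway `PATH_01` draws its members
#'   with 5x weight from the most abundant transcripts.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_transcripts = 200L,
                              length_range = c(300L, 3000L),
                              n_toxin_genes = 20L,
                              toxin_scaffolds = list(
                                SCAF_A = c(3L, 3L, 6L, 3L),
                                SCAF_B = c(6L, 6L, 0L, 5L, 4L),
                                SCAF_C = c(5L, 6L, 3L, 8L, 2L)),
                              divergence = 0.1,
                              mutate_cys = FALSE,
                              abundance_law = 1.75,
                              read_length = 90L,
                              n_reads = 5e5,
                              error_rate = 0.01,
                              n_pathways = 20L,
                              pathway_size = 15L,
                              enriched_pathway = TRUE) {
  cfg <- list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
              length_range = as.integer(length_range),
              n_toxin_genes = as.integer(n_toxin_genes),
              toxin_scaffolds = toxin_scaffolds, divergence = divergence,
              mutate_cys = isTRUE(mutate_cys), abundance_law = abundance_law,
              read_length = as.integer(read_length),
              n_reads = as.integer(n_reads), error_rate = error_rate,
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              enriched_pathway = isTRUE(enriched_pathway))
  if (length(cfg$length_range) != 2L || cfg$length_range[1] > cfg$length_range[2])
    stop("length_range must be an increasing bp interval")
  if (cfg$length_range[1] < 150L)
    stop("length_range minimum must be >= 150 bp so a >=40 aa ORF fits")
  if (cfg$divergence < 0 || cfg$divergence > 1)
    stop("divergence must lie in [0,1]")
  if (cfg$error_rate < 0 || cfg$error_rate > 1)
    stop("error_rate must lie in [0,1]")
  if (cfg$n_toxin_genes > cfg$n_transcripts)
    stop("n_toxin_genes cannot exceed n_transcripts")
  if (!length(cfg$toxin_scaffolds) && cfg$n_toxin_genes > 0L)
    stop("toxin_scaffolds must be non-empty when toxin genes are requested")
  if (is.null(names(cfg$toxin_scaffolds)))
    names(cfg$toxin_scaffolds) <- sprintf("SCAF_%02d",
                                          seq_along(cfg$toxin_scaffolds))
  class(cfg) <- "simulation_config"
  cfg
}

.sample_aa <- function(n, exclude = character()) {
  pool <- setdiff(.AA20, exclude)
  sample(pool, n, replace = TRUE)
}

# one nucleotide codon per amino acid, sampled among synonymous non-stop codons
.codons_for <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), as.character(gc))
})

.encode_aa <- function(aa) {
  vapply(aa, function(a) {
    cods <- .codons_for[[a]]
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, character(1), USE.NAMES = FALSE)
}

.scaffold_aa <- function(gaps) {
  # C, then for each gap g: g non-cysteine residues and the next C
  parts <- "C"
  for (g in gaps) parts <- c(parts, .sample_aa(g, exclude = "C"), "C")
  parts
}

# UTR without any ATG, so the planted ORF stays the principal one
.utr_no_atg <- function(n) {
  if (n == 0L) return("")
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    if (!grepl("ATG", s, fixed = TRUE)) return(s)
  }
}

.mutate_protein <- function(aa, divergence, mutate_cys) {
  if (divergence == 0) return(aa)
  hit <- stats::runif(length(aa)) < divergence
  if (!mutate_cys) hit[aa == "C"] <- FALSE
  idx <- which(hit)
  for (i in idx) {
    excl <- if (mutate_cys) aa[i] else c(aa[i], "C")
    aa[i] <- sample(setdiff(.AA20, excl), 1L)
  }
  aa
}

#' Generate a synthetic transcriptome with ground truth
#'
#' Each transcript carries exactly one planted principal ORF (ATG ... stop)
#' on a recorded strand; untranslated flanks are ATG-free so the planted
#' ORF is the longest product with a reference homologue.  Reference
#' proteins are the planted translations mutated per-site at rate
#' `divergence`.  Toxin genes embed a cysteine-spacing scaffold and, where
#' the family has one, a domain architecture; their non-scaffold residues
#' avoid cysteine so the extracted skeleton equals the planted scaffold.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_transcriptome`:
#'   `transcripts` (named character), `proteins` (planted translations),
#'   `reference` (named character, the divergent known-protein database),
#'   `ref_meta` (data frame: ref_id, source, family, category, is_toxin),
#'   `domains` / `ref_architectures` (domain annotation tables),
#'   `pathways` (protein_id/term_id map) and `truth` (abundance weights,
#'   ORF coordinates, toxin labels, pathway memberships).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  ids <- sprintf("T%04d", seq_len(n))
  toxin_idx <- if (config$n_toxin_genes > 0L)
    sort(sample.int(n, config$n_toxin_genes)) else integer()
  scaffold_ids <- names(config$toxin_scaffolds)

  transcripts <- character(n)
  proteins <- character(n)
  orf <- data.frame(transcript_id = ids, nt_start = 0L, nt_end = 0L,
                    strand = "+", stringsAsFactors = FALSE)
  tox <- data.frame(transcript_id = character(), protein_id = character(),
                    scaffold_id = character(), family = character(),
                    category = character(), stringsAsFactors = FALSE)
  domains <- list(); fam_cycle <- names(.FAMILY_CATEGORY)

  for (i in seq_len(n)) {
    L <- config$length_range[1] +
      sample.int(config$length_range[2] - config$length_range[1] + 1L, 1L) - 1L
    max_utr <- min(30L, (L - 126L) %/% 2L)
    utr5 <- sample.int(max_utr + 1L, 1L) - 1L
    utr3 <- sample.int(max_utr + 1L, 1L) - 1L
    aa_len <- (L - utr5 - utr3 - 3L) %/% 3L  # excludes start? includes M
    is_tox <- i %in% toxin_idx
    if (is_tox) {
      k <- match(i, toxin_idx)
      scaf_id <- scaffold_ids[((k - 1L) %% length(scaffold_ids)) + 1L]
      gaps <- config$toxin_scaffolds[[scaf_id]]
      scaf <- .scaffold_aa(gaps)
      body_len <- aa_len - 1L - length(scaf)
      if (body_len < 2L) stop("transcript too short to host scaffold ", scaf_id)
      at <- sample.int(body_len - 1L, 1L)
      body <- c(.sample_aa(at, exclude = "C"), scaf,
                .sample_aa(body_len - at, exclude = "C"))
      fam <- fam_cycle[((k - 1L) %% length(fam_cycle)) + 1L]
      tox <- rbind(tox, data.frame(
        transcript_id = ids[i], protein_id = paste0("P_", ids[i]),
        scaffold_id = scaf_id, family = fam,
        category = unname(.FAMILY_CATEGORY[fam]), stringsAsFactors = FALSE))
      arch <- .FAMILY_ARCHITECTURE[[fam]]
      if (!is.null(arch)) {
        # evenly spaced non-overlapping domain intervals over the protein
        w <- max(5L, (aa_len - 2L) %/% (2L * length(arch)))
        st <- seq(2L, by = 2L * w, length.out = length(arch))
        domains[[length(domains) + 1L]] <- data.frame(
          protein_id = paste0("P_", ids[i]), domain_id = arch,
          start = st, end = st + w, score = 100,
          stringsAsFactors = FALSE)
      }
    } else {
      body <- .sample_aa(aa_len - 1L)
    }
    aa <- c("M", body)
    cds <- paste(c("ATG", .encode_aa(body),
                   sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
    fwd <- paste0(.utr_no_atg(utr5), cds, .utr_no_atg(utr3))
    Lf <- nchar(fwd)
    s0 <- utr5; s1 <- utr5 + 3L * (aa_len + 1L)
    if (stats::runif(1) < 0.5) {
      transcripts[i] <- .revcomp(fwd)
      orf$nt_start[i] <- Lf - s1; orf$nt_end[i] <- Lf - s0
      orf$strand[i] <- "-"
    } else {
      transcripts[i] <- fwd
      orf$nt_start[i] <- s0; orf$nt_end[i] <- s1
    }
    proteins[i] <- paste(aa, collapse = "")
  }
  names(transcripts) <- ids
  names(proteins) <- paste0("P_", ids)

  reference <- vapply(proteins, function(p) {
    paste(.mutate_protein(strsplit(p, "")[[1]], config$divergence,
                          config$mutate_cys), collapse = "")
  }, character(1))
  names(reference) <- paste0("REF_", ids)
  ref_meta <- data.frame(ref_id = names(reference), source = ids,
                         family = NA_character_, category = NA_character_,
                         is_toxin = ids %in% ids[toxin_idx],
                         stringsAsFactors = FALSE)
  if (nrow(tox)) {
    j <- match(tox$transcript_id, ref_meta$source)
    ref_meta$family[j] <- tox$family
    ref_meta$category[j] <- tox$category
  }

  # abundance: power law over a random rank permutation
  ranks <- sample.int(n)
  w <- ranks^(-config$abundance_law)
  w <- w / sum(w)
  names(w) <- ids

  # pathway membership over planted protein ids; PATH_01 is optionally
  # biased 5x toward the most abundant transcripts
  pids <- paste0("P_", ids)
  pws <- lapply(seq_len(config$n_pathways), function(p) {
    prob <- rep(1, n)
    if (p == 1L && config$enriched_pathway)
      prob[rank(-w, ties.method = "first") <= n %/% 4L] <- 5
    data.frame(protein_id = sample(pids, min(config$pathway_size, n),
                                   prob = prob),
               term_id = sprintf("PATH_%02d", p), stringsAsFactors = FALSE)
  })
  pathways <- do.call(rbind, pws)

  out <- list(transcripts = transcripts, proteins = proteins,
              reference = reference, ref_meta = ref_meta,
              domains = if (length(domains)) do.call(rbind, domains) else
                data.frame(protein_id = character(), domain_id = character(),
                           start = integer(), end = integer(),
                           score = numeric(), stringsAsFactors = FALSE),
              ref_architectures = .reference_architectures(),
              pathways = pathways,
              truth = list(abundance = w, orfs = orf, toxins = tox,
                           pathways = pathways),
              config = config)
  class(out) <- "synthetic_transcriptome"
  out
}

.reference_architectures <- function() {
  fams <- names(.FAMILY_ARCHITECTURE)
  do.call(rbind, lapply(fams, function(f) {
    data.frame(family = f,
               architecture = paste(.FAMILY_ARCHITECTURE[[f]],
                                    collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Draw reads from a synthetic transcriptome
#'
#' Reads are assigned to transcripts multinomially with probability
#' proportional to abundance weight times transcript length, start
#' positions uniform over the eligible range, and per-base substitution
#' errors at `error_rate`.  Emitted both as SAM-style alignment records and
#' as a per-transcript count table whose counts sum to `n_reads`.
#'
#' @param sim A `synthetic_transcriptome` from [generate_transcriptome()].
#' @param config Optional [simulation_config()]; defaults to `sim$config`.
#' @return List with `records` (data frame: qname, flag, rname, pos, seq),
#'   `counts` (data frame: transcript_id, count) and `lengths` (named
#'   integer vector).
#' @export
generate_reads <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "synthetic_transcriptome"))
  set.seed(config$seed + 1000003L)
  w <- sim$truth$abundance
  if (abs(sum(w) - 1) > 1e-9) stop("abundance weights must be normalized")
  lens <- nchar(sim$transcripts)
  rl <- config$read_length
  short <- names(lens)[lens < rl]
  if (length(short))
    stop("read_length ", rl, " exceeds the length of transcript ", short[1])
  p <- w * lens
  cnt <- as.vector(stats::rmultinom(1L, config$n_reads, p))
  names(cnt) <- names(lens)

  recs <- vector("list", length(lens))
  ridx <- 0L
  for (i in seq_along(lens)) {
    k <- cnt[i]
    if (k == 0L) next
    starts <- sample.int(lens[i] - rl + 1L, k, replace = TRUE)
    seqs <- substring(sim$transcripts[i], starts, starts + rl - 1L)
    recs[[i]] <- data.frame(qname = sprintf("READ_%s_%06d", names(lens)[i],
                                            seq_len(k) + ridx),
                            flag = 0L, rname = names(lens)[i],
                            pos = starts, seq = seqs,
                            stringsAsFactors = FALSE)
    ridx <- ridx + k
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(qname = character(), flag = integer(), rname = character(),
               pos = integer(), seq = character(), stringsAsFactors = FALSE)
  if (config$error_rate > 0 && nrow(records))
    records$seq <- .add_read_errors(records$seq, rl, config$error_rate)
  list(records = records,
       counts = data.frame(transcript_id = names(cnt),
                           count = as.integer(cnt),
                           stringsAsFactors = FALSE),
       lengths = lens)
}

# vectorized per-base substitution errors; multiple errors within one read
# are applied in occurrence rounds so in-place substr assignment stays valid
.add_read_errors <- function(seqs, rl, error_rate) {
  bases <- c("A", "C", "G", "T")
  nerr <- stats::rbinom(length(seqs), rl, error_rate)
  tot <- sum(nerr)
  if (tot == 0L) return(seqs)
  rid <- rep.int(seq_along(seqs), nerr)
  pos <- sample.int(rl, tot, replace = TRUE)
  occ <- stats::ave(rid, rid, FUN = seq_along)
  shift <- sample.int(3L, tot, replace = TRUE)
  for (g in seq_len(max(occ))) {
    sel <- occ == g
    idx <- rid[sel]
    p <- pos[sel]
    tmp <- seqs[idx]
    old <- match(substring(tmp, p, p), bases)
    substr(tmp, p, p) <- bases[(old + shift[sel] - 1L) %% 4L + 1L]
    seqs[idx] <- tmp
  }
  seqs
}

#' Write all synthetic-run files to a directory
#'
#' Emits transcripts and reference FASTA, reference metadata, domain and
#' architecture tables, the pathway map, the ground-truth sidecar, the SAM
#' alignment file and the count table.
#'
#' @param sim A `synthetic_transcriptome`.
#' @param reads Output of [generate_reads()], or `NULL` to skip reads.
#' @param dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, reads = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- c(transcripts = file.path(dir, "transcripts.fasta"),
         reference = file.path(dir, "reference.fasta"),
         ref_meta = file.path(dir, "reference_meta.tsv"),
         domains = file.path(dir, "domains.tsv"),
         architectures = file.path(dir, "ref_architectures.tsv"),
         pathways = file.path(dir, "pathways.tsv"),
         truth_orfs = file.path(dir, "truth_orfs.tsv"),
         truth_abundance = file.path(dir, "truth_abundance.tsv"),
         truth_toxins = file.path(dir, "truth_toxins.tsv"))
  write_fasta(sim$transcripts, p["transcripts"], "DNA")
  write_fasta(sim$reference, p["reference"], "AA")
  write_tsv(sim$ref_meta, p["ref_meta"])
  write_tsv(sim$domains, p["domains"])
  write_tsv(sim$ref_architectures, p["architectures"])
  write_tsv(sim$pathways, p["pathways"])
  write_tsv(sim$truth$orfs, p["truth_orfs"])
  write_tsv(data.frame(transcript_id = names(sim$truth$abundance),
                       weight = as.numeric(sim$truth$abundance),
                       stringsAsFactors = FALSE), p["truth_abundance"])
  write_tsv(sim$truth$toxins, p["truth_toxins"])
  if (!is.null(reads)) {
    p <- c(p, sam = file.path(dir, "reads.sam"),
           counts = file.path(dir, "counts.tsv"))
    write_sam(reads$records, reads$lengths, p["sam"])
    write_tsv(reads$counts, p["counts"])
  }
  invisible(p)
}
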