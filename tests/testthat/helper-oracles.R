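# Independent oracles and small fixture builders used across the suite.

# Brute-force six-frame ORF scan: tries every position on both strands for
# "ATG" and walks codons one by one.  Deliberately naive and independent of
# the package implementation.
oracle_orfs <- function(seq, min_len_aa) {
  gc <- Biostrings::GENETIC_CODE
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    L <- nchar(s)
    p <- 1L
    while (p + 2L <= L) {
      if (substr(s, p, p + 2L) == "ATG") {
        aa <- character()
        q <- p
        full <- FALSE
        while (q + 2L <= L) {
          cod <- substr(s, q, q + 2L)
          a <- if (grepl("N", cod)) "X" else unname(gc[cod])
          if (!is.na(a) && a == "*") { full <- TRUE; break }
          aa <- c(aa, if (is.na(a)) "X" else a)
          q <- q + 3L
        }
        naa <- length(aa)
        if (naa >= min_len_aa) {
          st <- p - 1L
          en <- st + 3L * naa + if (full) 3L else 0L
          if (strand == "-") { tmp <- st; st <- L - en; en <- L - tmp }
          rows[[length(rows) + 1L]] <- data.frame(
            strand = strand, nt_start = st, nt_end = en,
            aa = paste(aa, collapse = ""), is_full_length = full,
            stringsAsFactors = FALSE)
        }
      }
      p <- p + 1L
    }
  }
  if (!length(rows)) {
    return(data.frame(strand = character(), nt_start = integer(),
                      nt_end = integer(), aa = character(),
                      is_full_length = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$strand, out$nt_start, out$nt_end, out$aa), , drop = FALSE]
}

orf_key <- function(df) {
  sort(paste(df$strand, df$nt_start, df$nt_end, df$aa, df$is_full_length))
}

# Hypergeometric upper tail by explicit binomial-coefficient sum.
oracle_hyper_sum <- function(N, M, n, m) {
  if (m == 0) return(1)
  i <- m:min(M, n)
  i <- i[n - i <= N - M]
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n)
# samples (tiny N only).
oracle_hyper_enum <- function(N, M, n, m) {
  if (n == 0) return(if (m == 0) 1 else 0)
  samples <- utils::combn(N, n)
  mean(colSums(samples <= M) >= m)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_aa <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# small simulation used by several files
tiny_sim <- function(seed = 3L, n = 25L, n_tox = 6L, divergence = 0,
                     n_reads = 2e4) {
  generate_transcriptome(simulation_config(
    seed = seed, n_transcripts = n, n_toxin_genes = n_tox,
    divergence = divergence, n_reads = n_reads))
}

# a minimal hit row with metrics, for classify/merge tests
hit_row <- function(ml_bl, ml_pl, identity, bait = "b", prey = "p",
                    evalue = 1e-10) {
  data.frame(bait_id = bait, prey_id = prey, ML = 100L, BL = 100L,
             PL = 100L, ml_bl = ml_bl, ml_pl = ml_pl, identity = identity,
             evalue = evalue, stringsAsFactors = FALSE)
}
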