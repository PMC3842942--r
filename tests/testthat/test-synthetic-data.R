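test_that("configuration invariants are enforced", {
  expect_error(simulation_config(length_range = c(100, 500)), ">= 150")
  expect_error(simulation_config(length_range = c(500, 300)), "increasing")
  expect_error(simulation_config(divergence = 1.5), "divergence")
  expect_error(simulation_config(n_transcripts = 5, n_toxin_genes = 6),
               "n_toxin_genes")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- simulation_config(seed = 1, n_transcripts = 15, n_toxin_genes = 3,
                           n_reads = 5000)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  s1 <- generate_transcriptome(cfg); r1 <- generate_reads(s1)
  s2 <- generate_transcriptome(cfg); r2 <- generate_reads(s2)
  p1 <- write_simulation(s1, r1, d1)
  p2 <- write_simulation(s2, r2, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), info = k)
  }
})

test_that("weights normalize and counts are conserved", {
  sim <- tiny_sim(seed = 2, n = 20, n_reads = 30000)
  expect_lt(abs(sum(sim$truth$abundance) - 1), 1e-12)
  expect_true(all(sim$truth$abundance >= 0))
  reads <- generate_reads(sim)
  expect_equal(sum(reads$counts$count), 30000L)
  expect_equal(nrow(reads$records), 30000L)
})

test_that("every transcript hosts exactly its planted principal ORF", {
  sim <- tiny_sim(seed = 9, n = 20)
  orfs <- sim$truth$orfs
  for (i in seq_len(nrow(orfs))) {
    s <- sim$transcripts[[orfs$transcript_id[i]]]
    cds <- substr(s, orfs$nt_start[i] + 1, orfs$nt_end[i])
    if (orfs$strand[i] == "-") cds <- revcomp_chr(cds)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
    aa <- six_frame_orfs("c", cds, min_len_aa = 1)
    aa <- aa[aa$strand == "+" & aa$nt_start == 0, ]
    expect_equal(aa$aa, unname(sim$proteins[paste0("P_", orfs$transcript_id[i])]))
  }
})

test_that("divergence 0 reproduces reference proteins exactly", {
  sim <- tiny_sim(seed = 4, n = 15, divergence = 0)
  expect_identical(unname(sim$proteins), unname(sim$reference))
  hits <- homology_search(sim$proteins, sim$reference)
  hits <- compute_hit_metrics(hits,
                              stats::setNames(nchar(sim$proteins),
                                              names(sim$proteins)),
                              stats::setNames(nchar(sim$reference),
                                              names(sim$reference)))
  bh <- best_hits(hits)
  expect_equal(nrow(bh), length(sim$proteins))
  expect_true(all(bh$identity == 100))
  expect_true(all(bh$ml_bl == 1))
  expect_true(all(bh$ml_pl == 1))
})

test_that("mean best-hit identity tracks the per-site Bernoulli expectation", {
  # each mutated site changes the residue, so expected identity is
  # 100 * (1 - divergence); the simulation mean must sit within +-5 points
  sim <- generate_transcriptome(simulation_config(
    seed = 12, n_transcripts = 200, n_toxin_genes = 20, divergence = 0.3))
  hits <- homology_search(sim$proteins, sim$reference)
  bh <- best_hits(hits)
  expect_equal(nrow(bh), 200L)
  expect_lt(abs(mean(bh$identity) - 70), 5)
  expect_lt(abs(stats::median(bh$identity) - 70), 5)
})

test_that("reads follow the planted abundances", {
  sim <- tiny_sim(seed = 6, n = 2, n_tox = 0, n_reads = 1000)
  # all mass on transcript 1
  sim$truth$abundance <- stats::setNames(c(1, 0), names(sim$truth$abundance))
  reads <- generate_reads(sim)
  expect_equal(reads$counts$count[1], 1000L)
  expect_equal(reads$counts$count[2], 0L)

  # equal weights, equal lengths: binomial 3-sigma around n/2
  cfg <- simulation_config(seed = 8, n_transcripts = 2, n_toxin_genes = 0,
                           length_range = c(500, 500), n_reads = 1e5)
  sim2 <- generate_transcriptome(cfg)
  sim2$truth$abundance <- stats::setNames(c(0.5, 0.5),
                                          names(sim2$truth$abundance))
  r2 <- generate_reads(sim2)
  expect_lt(abs(r2$counts$count[1] - 5e4), 3 * sqrt(1e5 * 0.25))
})

test_that("read_length longer than the shortest transcript is rejected", {
  sim <- tiny_sim(seed = 13, n = 5, n_tox = 0)
  cfg <- sim$config
  cfg$read_length <- min(nchar(sim$transcripts)) + 1L
  shortest <- names(which.min(nchar(sim$transcripts)))
  expect_error(generate_reads(sim, cfg), shortest)
})

test_that("planted toxin scaffolds are literally present (divergence 0)", {
  sim <- tiny_sim(seed = 10, n = 20, n_tox = 8, divergence = 0)
  tox <- sim$truth$toxins
  expect_equal(nrow(tox), 8L)
  for (i in seq_len(nrow(tox))) {
    gaps <- sim$config$toxin_scaffolds[[tox$scaffold_id[i]]]
    pat <- extract_cys_pattern(sim$proteins[[tox$protein_id[i]]])
    # toxin ORFs carry no cysteines outside the scaffold, so extraction
    # returns the planted scaffold exactly
    expect_equal(pat$gaps, as.integer(gaps), info = tox$protein_id[i])
  }
})

test_that("divergence preserves cysteines unless mutate_cys is set", {
  cfg <- simulation_config(seed = 14, n_transcripts = 30, n_toxin_genes = 10,
                           divergence = 0.3)
  sim <- generate_transcriptome(cfg)
  count_c <- function(x) lengths(regmatches(x, gregexpr("C", x)))
  expect_equal(count_c(unname(sim$proteins)), count_c(unname(sim$reference)))
})
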