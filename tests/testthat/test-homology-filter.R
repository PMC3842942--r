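test_that("hit metrics are derived correctly and capped at 1", {
  hits <- data.frame(bait_id = "b", prey_id = "p", ML = 90L,
                     identity = 50, evalue = 1e-20,
                     stringsAsFactors = FALSE)
  h <- compute_hit_metrics(hits, c(b = 100), c(p = 120))
  expect_equal(h$ml_bl, 0.9)
  expect_equal(h$ml_pl, 0.75)
  expect_equal(h$identity, 50)

  # gapped local alignments can exceed either length; ratios cap at 1
  hits$ML <- 130L
  h2 <- compute_hit_metrics(hits, c(b = 100), c(p = 120))
  expect_equal(h2$ml_bl, 1.0)
  expect_equal(h2$ml_pl, 1.0)

  expect_error(compute_hit_metrics(hits, c(x = 100), c(p = 120)), "b")
  expect_error(compute_hit_metrics(hits, c(b = 0), c(p = 120)), "positive")
})

test_that("tier classification uses strict inequalities", {
  expect_true(classify_hits(hit_row(0.51, 0.51, 31), "core"))
  expect_false(classify_hits(hit_row(0.5, 0.9, 99), "core"))
  expect_true(classify_hits(hit_row(0.85, 0.92, 55), "high"))
  expect_false(classify_hits(hit_row(0.8, 0.92, 55), "high"))
  expect_true(classify_hits(hit_row(0.6, 0.6, 81), "full_length_unique"))
  # est_match_strict constrains bait-side coverage and identity only
  expect_true(classify_hits(hit_row(0.81, 0.1, 96), "est_match_strict"))
  expect_error(classify_hits(hit_row(1, 1, 100), "nonsense"), "unknown")
})

test_that("classification is monotone in every metric", {
  set.seed(21)
  tiers <- confidence_tiers()
  for (i in 1:300) {
    h <- hit_row(runif(1), runif(1), runif(1, 0, 100))
    for (tn in names(tiers)) {
      base <- classify_hits(h, tn)
      up <- h
      j <- sample(c("ml_bl", "ml_pl", "identity"), 1)
      up[[j]] <- up[[j]] + runif(1, 0, if (j == "identity") 50 else 0.5)
      if (base) expect_true(classify_hits(up, tn))
    }
  }
})

test_that("best candidate selection follows the longest-with-homologue rule", {
  cands <- data.frame(
    transcript_id = "t", candidate_id = c("a", "b"),
    aa = c(strrep("A", 50), strrep("A", 80)), aa_len = c(50L, 80L),
    is_full_length = c(TRUE, TRUE), stringsAsFactors = FALSE)
  hits <- data.frame(bait_id = "a", prey_id = "p", ML = 50L, identity = 99,
                     evalue = 1e-10, stringsAsFactors = FALSE)
  # the 50-aa candidate is the longest WITH a homologue
  sel <- select_best_candidate(cands, hits)
  expect_equal(sel$candidate_id, "a")
  expect_equal(sel$best_prey, "p")

  # no hits below the cutoff: longest overall, no prey
  sel2 <- select_best_candidate(cands, hits, e_cut = 1e-20)
  expect_equal(sel2$candidate_id, "b")
  expect_true(is.na(sel2$best_prey))

  expect_error(select_best_candidate(cands[0, ], hits), "empty")
})

test_that("selection agrees with a brute-force re-scan on random instances", {
  set.seed(31)
  for (i in 1:300) {
    k <- sample(2:6, 1)
    cands <- data.frame(
      transcript_id = "t",
      candidate_id = paste0("c", sample(100, k)),
      aa_len = sample(40:120, k, replace = TRUE),
      is_full_length = sample(c(TRUE, FALSE), k, replace = TRUE),
      stringsAsFactors = FALSE)
    nh <- sample(0:4, 1)
    hits <- data.frame(
      bait_id = sample(cands$candidate_id, 4, replace = TRUE),
      prey_id = paste0("p", sample(5, 4, replace = TRUE)),
      ML = 50L, identity = 50,
      evalue = 10^runif(4, -12, 0),
      stringsAsFactors = FALSE)[seq_len(nh), , drop = FALSE]
    sel <- select_best_candidate(cands, hits, e_cut = 1e-5)
    # oracle: filter candidates with a hit < cutoff, else all; then sort
    with_hit <- unique(hits$bait_id[hits$evalue < 1e-5])
    pool <- cands[cands$candidate_id %in% with_hit, ]
    if (!nrow(pool)) pool <- cands
    pool <- pool[order(-pool$aa_len, -pool$is_full_length,
                       pool$candidate_id), ]
    expect_equal(sel$candidate_id, pool$candidate_id[1])
  }
})

test_that("redundancy merging collapses by shared best prey", {
  sel <- data.frame(
    transcript_id = paste0("t", 1:3),
    candidate_id = c("c1", "c2", "c3"),
    aa_len = c(100L, 90L, 80L),
    is_full_length = TRUE,
    best_prey = "X", stringsAsFactors = FALSE)
  m <- merge_redundant(sel)
  expect_equal(nrow(m), 1L)
  expect_equal(m$aa_len, 100L)
  expect_equal(m$n_members, 3L)

  sel$best_prey <- c("X", "Y", NA)
  m2 <- merge_redundant(sel)
  expect_equal(nrow(m2), 3L)
  expect_true(all(m2$n_members == 1L))
})

test_that("merging is idempotent and order-independent", {
  set.seed(41)
  for (i in 1:100) {
    k <- sample(2:10, 1)
    sel <- data.frame(
      transcript_id = paste0("t", seq_len(k)),
      candidate_id = paste0("c", sample(1000, k)),
      aa_len = sample(40:200, k, replace = TRUE),
      is_full_length = sample(c(TRUE, FALSE), k, replace = TRUE),
      best_prey = sample(c(NA, paste0("p", 1:3)), k, replace = TRUE),
      stringsAsFactors = FALSE)
    m1 <- merge_redundant(sel)
    expect_identical(merge_redundant(m1), m1)
    perm <- sel[sample(k), ]
    expect_identical(merge_redundant(perm), m1)
  }
})

test_that("QC against a reference set floors percentages and counts lengths", {
  # 961 matched of 1015, as pure arithmetic on a constructed hit table
  hits <- data.frame(bait_id = paste0("est", 1:961), prey_id = "a",
                     ML = 100L, BL = 100L, PL = 110L, ml_bl = 1, ml_pl = 0.9,
                     identity = 96, evalue = 1e-30, stringsAsFactors = FALSE)
  qc <- qc_against_reference(hits, n_bait = 1015)
  expect_equal(qc$matched, 961L)
  expect_equal(qc$matched_pct, 94)
  expect_equal(qc$strict, 961L)
  expect_equal(qc$bait_shorter, 961L)
  expect_error(qc_against_reference(hits, 0), "empty")
})

test_that("identical sequences give 100% matched and strict QC", {
  set.seed(51)
  ests <- stats::setNames(vapply(1:12, function(i) random_aa(80),
                                 character(1)), paste0("est", 1:12))
  hits <- homology_search(ests, ests)
  hits <- compute_hit_metrics(hits, nchar(ests), nchar(ests))
  qc <- qc_against_reference(hits, n_bait = length(ests))
  expect_equal(qc$matched_pct, 100)
  expect_equal(qc$strict_pct, 100)
})

test_that("reversed baits form a clean negative control", {
  sim <- tiny_sim(seed = 16, n = 30, divergence = 0.1)
  rev_baits <- vapply(sim$proteins, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1))
  fwd <- homology_search(sim$proteins, sim$reference)
  ctrl <- homology_search(rev_baits, sim$reference)
  qc <- qc_against_reference(
    compute_hit_metrics(fwd, nchar(sim$proteins), nchar(sim$reference)),
    n_bait = length(sim$proteins), control_hits = ctrl)
  expect_equal(qc$matched, 30L)
  expect_lt(qc$control_matched, 2L)
})
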