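test_that("cysteine patterns extract, render and parse consistently", {
  expect_equal(extract_cys_pattern("CAAACAAAC")$gaps, c(3L, 3L))
  # C at positions 4, 6, 10: one residue then three between cysteines
  expect_equal(extract_cys_pattern("MKWCACDEFC")$gaps, c(1L, 3L))
  expect_equal(render_cys_pattern(c(3L, 3L)), "C#C#C")
  expect_equal(render_cys_pattern(c(4L, 0L)), "C#xCC")
  # fewer than two cysteines: empty-pattern sentinel
  expect_length(extract_cys_pattern("MKWAAA")$gaps, 0L)
  expect_length(extract_cys_pattern("MKWCAA")$gaps, 0L)

  set.seed(71)
  for (i in 1:200) {
    gaps <- sample(0:12, sample(1:6, 1), replace = TRUE)
    expect_equal(parse_cys_pattern(render_cys_pattern(gaps))$gaps,
                 as.integer(gaps))
    pat <- extract_cys_pattern(random_aa(sample(20:120, 1)))
    if (length(pat$gaps))
      expect_equal(parse_cys_pattern(render_cys_pattern(pat))$gaps,
                   pat$gaps)
  }
})

test_that("pattern matching anchors on the cysteine skeleton", {
  expect_equal(match_pattern("MKCAAACAAACW", c(3L, 3L)), 2L)
  expect_length(match_pattern("CACAC", c(3L, 3L), tolerance = 0), 0L)
  expect_equal(match_pattern("CACAC", c(3L, 3L), tolerance = 2), 0L)
  expect_warning(m <- match_pattern("CAAAC", integer()), "empty")
  expect_length(m, 0L)
  expect_error(match_pattern("CAAAC", c(3L), tolerance = -1), "tolerance")
})

test_that("every sequence matches its own extracted pattern; tolerance is monotone", {
  set.seed(72)
  for (i in 1:150) {
    s <- random_aa(sample(30:150, 1))
    pat <- extract_cys_pattern(s)
    if (!length(pat$gaps)) next
    expect_gte(length(match_pattern(s, pat, tolerance = 0)), 1L)
    g <- sample(0:8, sample(1:4, 1), replace = TRUE)
    m0 <- match_pattern(s, g, tolerance = 0)
    m1 <- match_pattern(s, g, tolerance = 1)
    m2 <- match_pattern(s, g, tolerance = 2)
    expect_true(all(m0 %in% m1))
    expect_true(all(m1 %in% m2))
  }
})

test_that("domain architectures match exactly and annotate splits", {
  ref <- data.frame(family = "ctenitoxin", architecture = "TY,TY",
                    stringsAsFactors = FALSE)
  two_ty <- data.frame(protein_id = "p", domain_id = c("TY", "TY"),
                       start = c(10L, 60L), end = c(40L, 90L),
                       stringsAsFactors = FALSE)
  expect_equal(match_domain_architecture(two_ty, ref)$family, "ctenitoxin")
  one_ty <- two_ty[1, ]
  expect_true(is.na(match_domain_architecture(one_ty, ref)$family))

  # 20 ANK repeats with a 60-residue gap after the 14th: split "14+6"
  w <- 33L
  starts <- cumsum(c(5L, rep(w, 19L))) + c(rep(0L, 14L), rep(60L, 6L))
  ank <- data.frame(protein_id = "q", domain_id = "ANK",
                    start = starts, end = starts + 30L,
                    stringsAsFactors = FALSE)
  m <- match_domain_architecture(ank,
         data.frame(family = "ANK_superfamily",
                    architecture = paste(rep("ANK", 20), collapse = ","),
                    stringsAsFactors = FALSE))
  expect_equal(m$split, "14+6")
  expect_equal(m$family, "ANK_superfamily")
})

test_that("overlapping domain intervals resolve to the higher score", {
  ref <- data.frame(family = "f", architecture = "A,B",
                    stringsAsFactors = FALSE)
  d <- data.frame(protein_id = "p", domain_id = c("A", "C", "B"),
                  start = c(1L, 5L, 40L), end = c(30L, 25L, 60L),
                  score = c(90, 10, 80), stringsAsFactors = FALSE)
  m <- match_domain_architecture(d, ref)
  expect_equal(m$architecture, "A,B")
  expect_equal(m$family, "f")
})

test_that("toxin calls union evidence channels and assign families", {
  proteins <- c(p1 = "MKWCAAACAAACAAAAAACAAACDD",  # SCAF_A-like knot
                p2 = paste0("M", strrep("A", 50)),
                p3 = paste0("M", strrep("G", 40)))
  hits <- data.frame(bait_id = "p2", prey_id = "TOX1", ML = 40L,
                     identity = 90, evalue = 1e-12, stringsAsFactors = FALSE)
  fams <- c(TOX1 = "lycotoxin")
  pats <- list(extract_cys_pattern("CAAACAAACAAAAAACAAAC", id = "k1"))
  calls <- call_toxins(proteins, toxin_hits = hits, toxin_families = fams,
                       patterns = pats)
  expect_setequal(calls$protein_id, c("p1", "p2"))
  expect_equal(calls$evidence[calls$protein_id == "p2"], "homology")
  expect_equal(calls$family[calls$protein_id == "p2"], "lycotoxin")
  expect_equal(calls$category[calls$protein_id == "p2"], "neurotoxin")
  # planted knot without homology: cys_pattern evidence, orphan family
  expect_equal(calls$evidence[calls$protein_id == "p1"], "cys_pattern")
  expect_equal(calls$family[calls$protein_id == "p1"], "orphan")
  expect_equal(calls$category[calls$protein_id == "p1"], "unknown")

  expect_error(call_toxins(proteins), "at least one evidence")
  # unknown family falls back to unknown category with a warning
  expect_warning(
    c2 <- call_toxins(proteins, toxin_hits = hits,
                      toxin_families = c(TOX1 = "weird_family")),
    "weird_family")
  expect_equal(c2$category, "unknown")
})

test_that("toxin calls are invariant under input permutation", {
  sim <- tiny_sim(seed = 19, n = 20, n_tox = 6, divergence = 0)
  tox_refs <- sim$reference[sim$ref_meta$ref_id[sim$ref_meta$is_toxin]]
  pats <- extract_pattern_library(tox_refs)
  hits <- homology_search(sim$proteins, tox_refs)
  fams <- stats::setNames(sim$ref_meta$family, sim$ref_meta$ref_id)
  a <- call_toxins(sim$proteins, hits, fams, patterns = pats)
  perm <- sample(length(sim$proteins))
  b <- call_toxins(sim$proteins[perm], hits[sample(nrow(hits)), ], fams,
                   patterns = rev(pats))
  expect_identical(a[c("protein_id", "evidence", "family", "category")],
                   b[c("protein_id", "evidence", "family", "category")])
})

test_that("planted scaffolds are recalled with a quiet shuffled null", {
  sim <- generate_transcriptome(simulation_config(
    seed = 20, n_transcripts = 60, n_toxin_genes = 15, divergence = 0.1))
  tox <- sim$truth$toxins
  pats <- lapply(sim$config$toxin_scaffolds, identity)
  # recall: every planted toxin protein matches its scaffold at tolerance 0
  hit <- vapply(seq_len(nrow(tox)), function(i)
    length(match_pattern(sim$proteins[[tox$protein_id[i]]],
                         pats[[tox$scaffold_id[i]]])) > 0, logical(1))
  expect_true(all(hit))
  # false positives on shuffled non-toxin proteins stay rare
  set.seed(99)
  others <- sim$proteins[setdiff(names(sim$proteins), tox$protein_id)]
  shuffled <- vapply(others, function(s)
    paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1))
  fp <- vapply(shuffled, function(s)
    any(vapply(pats, function(p) length(match_pattern(s, p)) > 0,
               logical(1))), logical(1))
  expect_lt(mean(fp), 0.05)
})

test_that("category summaries aggregate RPKM by functional class", {
  calls <- data.frame(protein_id = c("a", "b", "c"),
                      evidence = "homology",
                      family = c("trypsin", "trypsin", "SCP"),
                      category = c("protease", "protease", "neurotoxin"),
                      rpkm = c(10, 20, 5), stringsAsFactors = FALSE)
  s <- toxin_category_summary(calls)
  expect_equal(s$rpkm_sum[s$category == "protease"], 30)
  expect_equal(s$n[s$category == "protease"], 2L)
})
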