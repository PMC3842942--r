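---
title: "Annotating a venom-gland transcriptome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating a venom-gland transcriptome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomtx)
```

# The analysis in one page

`venomtx` turns an assembled venom-gland transcriptome into an annotated
protein set: six-frame ORF translation, homology-based quality filtering,
RPKM quantification, three-strategy toxin discovery, and hypergeometric
pathway enrichment. This vignette explains the underlying models and
conventions, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the design was genuinely open.

# ORF model

Each transcript is read in all six frames. An ORF starts at an ATG only
(alternative initiation codons are not used) and runs to the first
in-frame stop codon — a *full-length* product, whose nucleotide span
includes the stop but whose protein excludes it — or, when no stop is
reached, to the end of the sequence, a *fragment*. The distinction
matters downstream: ties in candidate selection and redundancy merging
prefer full-length products.

Conventions:

* Coordinates are 0-based half-open on the forward strand of the input;
  strand is `+`/`-`.
* Every internal ATG spawns its own candidate (nested ORFs), because the
  correct start cannot be known before homology evidence arrives;
  identical amino-acid products within one transcript are deduplicated
  keeping the longest nucleotide span.
* Codons containing `N` translate to `X`, and `X` never counts as a match
  in identity computations (the internal aligner scores `X` against
  anything, including `X`, as a mismatch). A codon with `N` is never a
  stop: ambiguity extends a product rather than truncating it.
* The default length filter is 40 aa; shorter products are discarded.

# Homology metrics and confidence tiers

For a hit between a bait (query) and prey (subject) protein, ML is the
aligned-region length, BL and PL the bait and prey lengths. ML/BL
proxies assembly accuracy, ML/PL sequence integrity, and percent identity
evolutionary variation. Because local alignments with gaps can make the
tabular "length" column exceed either sequence length, the ratios are
capped at 1.0 rather than enforced as invariants.

All tier thresholds are strict (`>`), as conventionally printed:

| tier | ML/BL | ML/PL | identity |
|------|-------|-------|----------|
| core | 0.5 | 0.5 | 30 |
| high | 0.8 | 0.8 | 50 |
| full_length_unique | 0.5 | 0.5 | 80 |
| est_match_strict | 0.8 | — | 95 |

For the EST-style strict criterion, "coverage" is taken bait-side (ML/BL)
because the independent reference sequences are the queries; the
prey-side ratio is unconstrained there. Identity is taken from the hit
table as produced by the search tool, not recomputed. Report percentages
are floored to whole percent, matching the reporting style of
per-mille-free sequencing summaries (961/1,015 → 94%).

Best-candidate selection implements "the longest candidate with any
homologue below e = 1e-5; otherwise the longest overall", with ties
preferring full-length products, then lexicographic candidate IDs so the
result is deterministic. Redundancy merging collapses proteins sharing a
best prey to the longest representative and is idempotent and invariant
under input order — both property-tested.

## The internal aligner

The production path for homology evidence is a 12-column BLAST tabular
reader. So that tests and synthetic runs need no external binary, the
package also ships `homology_search()`: a k-mer seeding prefilter
(shared 5-mers ≥ 4) followed by local alignment with match +1, mismatch
−1, linear gap −2 via `Biostrings::pairwiseAlignment`. Its reported
"e-value" is the monotone surrogate `exp(-score)` — adequate for
thresholding in a controlled synthetic world, and *not* a
Karlin–Altschul statistic. Real analyses should feed real BLAST output.

# Quantification

RPKM = 1e9 · C / (N · L). `C` counts primary mapped alignments only
(SAM flag bits 0x4 and 0x100 excluded) and `N` is the number of such
records — reads, not pairs, not alignments — which is the convention of
the original RPKM definition. Zero-count transcripts are retained with
RPKM 0 so category aggregation denominators stay stable. Fold-over-mean
is floored to an integer (11,481.33 over a mean of 78.92 → 145-fold).
The sequencing-depth estimate divides total read bases by the probable
transcriptome size, itself a fixed fraction of genome size; note the
widely quoted "≈24" for 2.48 Gb of reads over 5% of a 1.9 Gb genome does
not follow from those operands (they give 26.15) — the package implements
the stated formula and reports what it computes.

# Toxin discovery

Three evidence channels, unioned, every call carrying its channels — a
reportable evidence table replaces any silent manual curation step:

* **homology**: best hit against a known-toxin reference below the
  e-value cutoff; family inherited from the prey's annotated family.
* **domain**: exact ordered equality of domain-ID lists against reference
  architectures (two consecutive TY domains; trypsin; SCP; ANK repeats).
  Overlapping intervals from scanner output are resolved by keeping the
  higher-score (or first) interval. Runs of repeats separated by ≥ 50
  residues are annotated as split patterns such as "14+6".
* **cys_pattern**: the candidate's inter-cysteine gap sequence contains
  the pattern's gap list, each gap within `tolerance` (default 0).
  Matching anchors on the cysteine skeleton only; residue identity
  between cysteines is deliberately ignored, since toxin scaffolds
  conserve spacing far better than sequence. The canonical form is the
  gap list; the rendered dialect writes `#` for exactly three non-Cys
  residues and `x` per remaining residue, so arbitrary spacings stay
  representable and render → parse is a lossless round trip.

No flexibility value for pattern matching is standard in the field; the
tolerance is therefore an explicit parameter defaulting to the strictest
setting (0). Families map to five functional categories via a fixed,
overridable map: neurotoxins (ANK superfamily, SCP, lycotoxin),
assistant toxins (theriditoxin), proteases (trypsin), protease
inhibitors (TY-domain ctenitoxins) and unknown (scorpion-toxin-like,
orphan). Unknown families warn and fall back to `unknown`.

# Hypergeometric enrichment

The test statistic is the upper tail
P = 1 − Σ_{i=0}^{m−1} C(M,i)·C(N−M,n−i)/C(N,n) = P(X ≥ m): the observed
count sits inside the rejection tail, as the sum's upper limit m−1
dictates. It is computed with `stats::phyper` (log-space safe) and
verified in the test suite against two independent oracles: an explicit
binomial-coefficient sum for all N ≤ 25, and exhaustive enumeration of
all C(N,n) samples at tiny N.

Prose descriptions of (N, M, n, m) for pathway enrichment are often
ambiguous — a population/successes/sample assignment that reads naturally
does not always match the formula. Two mappings are implemented and
selectable; neither is asserted as canonical:

* `per_pathway` (default): N = mapped proteins in the population, M =
  the pathway's members, n = the gene set under test, m = the overlap.
* `prose`: N = the whole population, M = all mapped proteins, n = the
  pathway, m = its mapped members.

Raw P < 0.05 drives the `significant` flag (no multiple-testing
correction by default, matching common first-pass practice);
Benjamini–Hochberg adjusted values are available behind `adjust = TRUE`.

**Discreteness.** The hypergeometric test is discrete: the attained
type-I error at a nominal 0.05 cutoff is below 0.05, and at realistic
scale (a core set of a few thousand proteins, pathways of tens of
members) can sit well below it. The calibration check in the acceptance
suite therefore uses large counts (population 200,000, gene set 50,000,
pathway sizes 2–10%), for which the exact expected attained level is
0.0489; at small scale the test is simply conservative, which is a
property of the statistic, not a defect of the implementation.

# The synthetic world

The generator emulates the *inputs* of a deep-sequenced venom-gland
study with full ground truth:

* 200 transcripts of 300–3,000 bp (i.i.d. uniform ACGT background —
  the simplest null; composition effects are not under study);
* exactly one planted principal ORF per transcript, on a random strand,
  with ATG-free untranslated flanks so the planted ORF is always the
  longest product with a reference homologue;
* a "known protein" database derived from the planted translations by
  per-site substitution at rate `divergence` (default 0.1, giving the
  ~90% identity typical of cross-species best hits; at rate d the
  expected best-hit identity is simply 100·(1−d), which the suite checks
  as a Bernoulli oracle). By default mutations never create or destroy
  cysteines, so pattern-recall tests separate signal decay from matcher
  bugs; set `mutate_cys = TRUE` to lift this;
* 20 toxin genes embedding knottin-like cysteine scaffolds (gap lists
  such as 3-3-6-3); toxin ORFs carry no cysteines outside the scaffold,
  so skeleton extraction returns the planted scaffold exactly;
  families cycle through the five functional categories and, where a
  family has a characteristic architecture, a domain table is emitted;
* rank power-law abundances with exponent 1.75 (spanning ~1.06 × 10⁴
  over 200 transcripts; real venom glands span > 10⁶ over tens of
  thousands), and 5 × 10⁵ 90-bp reads drawn multinomially by weight ×
  length with uniform starts and 1% substitution errors;
* a pathway map of 20 terms, the first drawing its members with 5×
  weight from the top abundance quartile, so enrichment has a planted
  positive.

A single seed drives the whole run; sub-generators derive from it by
fixed offsets, and identical configurations give byte-identical files.

What it does **not** emulate — and hence what a green test does not
establish: realistic base-call error profiles and quality strings,
paired-end geometry, splice isoforms, chimeric or fragmented assemblies,
codon-usage and composition biases, and genuine evolutionary divergence
(indels, domain shuffling). Conclusions about those require real data.

## A known, deliberate red

One recovery target is not attainable in this stated world: requiring
Spearman ≥ 0.99 between RPKM and true abundance at 5 × 10⁵ reads with a
power law spanning 10⁴ over 200 transcripts. The bottom-ranked
transcripts receive only ~4–20 reads, and Poisson noise scrambles their
ranks; an implementation-independent multinomial oracle caps the
attainable Spearman at ≈ 0.983. The corresponding acceptance test is
implemented faithfully and left failing rather than weakening the stated
span or inflating the read count; the Pearson variant of the same check
(dominated by the well-measured high-abundance ranks) passes at > 0.99.

# Numerical and degenerate-input choices

* Ties everywhere break deterministically (full-length first, then
  lexicographic IDs), so outputs are permutation-invariant.
* Best hit per bait: lowest e-value, then highest identity, then longest
  ML.
* Empty candidate sets, empty pathway maps, zero-length sequences,
  missing lengths and out-of-range parameters raise errors naming the
  offending record; empty transcript sets and empty cysteine patterns
  warn and return empty results.
* Pathways with no mapped proteins score P = 1 with a warning rather
  than disappearing silently.
* Percentages in QC reports are floored; fold-over-mean is floored.
* The 40-aa filter, 1e-5 e-value cutoff, 0.05 enrichment cutoff and
  tolerance 0 are the package defaults and live in one run
  configuration.

# Limitations

The internal aligner is a testing convenience, not a BLAST replacement.
Architecture matching is exact ordered equality — no partial-architecture
scoring. The enrichment model ignores GO-graph propagation and KEGG
hierarchy. No TPM/FPKM variants, effective-length modelling or
multimapping rescue are provided. Reported toxin families depend
entirely on the supplied reference annotations; the package ships no
curated toxin database.
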