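---
title: "Models and methods behind peakcobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peakcobind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcobind)
```

`peakcobind` implements the downstream statistics of a transcription-factor
co-binding study: given called ChIP-seq peaks for CTCF, ER and FOXA1 across
breast cell lines, it asks where the factors bind together, whether those
overlaps are more frequent than genome structure alone would produce,
whether co-bound regions carry the factors' DNA motifs, where they sit
relative to genes, and whether differentially expressed genes cluster near
them. This vignette explains each model, its assumptions, the tunable
parameters, and the design choices made where a published description left
the method under-specified.

## Interval conventions and replicate consensus

All coordinates are 0-based half-open (BED convention); MACS-style 1-based
peak tables are converted on read and the summit offset is made absolute.
Two peaks overlap when they share **at least one base pair** on the same
chromosome; with half-open intervals, `[100, 200)` and `[200, 300)` do not
overlap. A binding region is *replicate-consistent* when a peak in
replicate 1 overlaps at least one peak of replicate 2.

Two decisions here were genuinely open:

* **Which coordinates survive consensus.** We anchor on replicate 1 and
  return its intervals unchanged (`keep = "rep1"`), because downstream
  counts then refer to actual called peaks. A `keep = "union"` variant
  merges each overlapping pair instead; its count can differ slightly, so
  both are exposed rather than guessed between.
* **Multi-line classes need an anchor too.** "Common" peaks across three
  cell lines are reported in the coordinates of a designated reference line
  (the first line by default). Counts depend mildly on that choice; the
  reference is recorded with the result.

Cell-line-specific peaks follow the strict definition: present in both
replicates of one line and in **no replicate** of any other line. The four
co-binding categories (CTCF+ER+FOXA1, CTCF+ER, CTCF+FOXA1, CTCF only)
partition the anchor CTCF set exactly because each anchor peak is assigned
once, by presence/absence of a one-base overlap with each partner set.
Overlap queries run on interval indexes (`GenomicRanges`); every operation
is property-tested against an all-pairs brute-force oracle, so the index is
an implementation detail, not a semantic one.

## Overlap significance: a block-rotation GSC variant

The question "is this much overlap surprising?" cannot be answered with a
uniform null: binding sites cluster in open chromatin, so shuffling peaks
uniformly overstates significance. The genome structural correction (GSC)
family of statistics addresses this by randomizing at the scale of large
genomic blocks so that local structure is preserved. The original method's
segmentation parameters are not fully specified in most applications, so
`peakcobind` implements an exactly specified, seedable member of that
family:

1. Partition each chromosome into consecutive blocks of `block_length`
   (default 1 Mb; for the 5-Mb synthetic chromosomes the pipeline uses
   500 kb, one tenth of the chromosome).
2. Assign every interval of the second set to the block containing its
   midpoint.
3. Per block, draw one uniform offset and rotate all midpoints of that
   block circularly; lengths, per-block counts and within-block clustering
   are preserved exactly.
4. Recount how many first-set peaks overlap the rotated set; repeat
   `iterations` times (default 10,000) and report the one-sided add-one
   empirical p-value `(1 + #{null >= observed}) / (iterations + 1)`.

The add-one rule means the smallest attainable p is `1/(iterations + 1)`:
claims like `p < 0.001` need at least 1,000 rotations, which is why the
power checks in the test suite run 2,000 iterations while the calibration
check (which only needs the *distribution* of p under independence) runs
500. The statistic is asymmetric — "how many A peaks touch B" — and the
pipeline reports both directions. `block_length` must be at least twice the
longest interval; rotated intervals may overhang block and chromosome edges
by less than half a peak width and are deliberately not clamped, since only
their positions enter the overlap count. Validation is by calibration: on
independent uniform peak sets the empirical p-values are uniform (the
fraction below 0.05 sits inside the binomial band around 0.05), and planted
co-binding drives p to the floor.

## Binned signal matrices

Heat-map data are built exactly as the classical recipe: a ±5 kb window
centred on each region midpoint, cut into 100 bins of 100 bp; each bin
counts treatment read 5′ starts, subtracts the same bin of the input
library, and both libraries are scaled to 10 million reads
(`1e7 / library_size` per read). Reads are counted by their 5′ start with no
fragment extension or strand shift. Windows are centred on the region
*midpoint* (matching "centre of the binding events" in figure legends), with
summit-centring available for motif-adjacent displays. Input subtraction
can leave negative bins; these are kept in the data (so that totals are
exactly the defined sums) and clamped at zero only when a heat map is
rendered. Whether one clamps before summing changes the total intensity
statistic, so `total_intensity()` exposes both via `clamp`. A zero-read
track contributes nothing rather than `0 * Inf`.

## Motif enrichment with a permuted-matrix null

The motif statistic asks not just "is the motif there?" but "*where* is it,
relative to the summit?". For each position weight matrix:

* 2 kb of sequence around each summit is scanned on both strands at every
  offset. The score of a window is the sum of per-column base frequencies
  (pseudocount 1 per cell before column normalization), min–max normalised:
  `similarity = (score - min) / (max - min)` where min/max are the sums of
  column-wise minimum/maximum frequencies. The consensus scores exactly 1,
  the anti-consensus 0, and matches are counted at similarity ≥ 0.85.
  "Similarity score" has no universal definition; this min–max convention
  was chosen because it is scale-free and makes the 85% threshold
  interpretable across matrices of different lengths and information
  content. Log-odds scoring is a documented alternative the scanner's
  threshold could be mapped onto, not a claim of equivalence with any other
  implementation.
* Match starts are pooled over all sequences into twenty 100-bp windows.
  A position matching on *both* strands counts as one site. This matters
  precisely for palindromes: a strand-symmetric matrix matches both strands
  at every hit, so counting strand-hits would double the observed count's
  variance relative to the permuted null (whose matrices are generally not
  palindromic — the expected count is permutation-invariant, the pairing is
  not), making outer windows anti-conservative. Site counting is a no-op
  for non-palindromic matrices and conservative for palindromes.
  `similarity_scan()` still reports every per-strand hit.
* The null re-scans everything with `n_perm` (default 1,000) random
  *column permutations* of the matrix. Permuting columns preserves the
  per-column composition and total information content — so the expected
  hit count under an i.i.d. background is unchanged — while destroying the
  base order that makes the motif a motif. The per-window p-value is the
  Gaussian upper-tail area at the observed count under the permuted-count
  distribution (sd with denominator n−1). A within-column shuffle would be
  the other defensible reading of "randomly permuted versions of the
  matrix"; column permutation was fixed as the default because it exactly
  preserves information content, which is the property the null needs.
* When the null is degenerate (all permuted counts equal), the p-value is 1
  if the observed count does not exceed the null mean, and the smallest
  positive double otherwise — a sentinel meaning "beyond every null
  sample", documented rather than hidden.

Because the Gaussian tail is an approximation to a discrete count
distribution, mild anti-conservatism is expected and is bounded in the test
suite (the type-I fraction at 0.05 stays within [0.01, 0.12] on motif-free
sequences). No multiple-testing correction is applied by default, matching
how windowed motif heat maps are usually reported; a Bonferroni option
exists. The scanner's inner loop is compiled (Rcpp) with a look-ahead bound
(skip a window as soon as the remaining columns cannot reach the
threshold); its results are property-tested against an exhaustive per-offset
recomputation in R.

The package ships a small **synthetic** PWM collection
(`inst/extdata/motifs_synthetic.jaspar`, also available as
`builtin_motifs()`): a GC-rich CTCF-like 14-mer, an ERE-like palindrome with
a degenerate 3-bp spacer, a forkhead-like 8-mer and two short distractors.
These are constructed stand-ins with realistic shapes, not curated database
matrices; `read_jaspar()` parses any JASPAR-format collection for real use.

## Genomic annotation

Peaks are classified promoter / exonic / intronic / intergenic by a single
anchor point (summit if recorded, else midpoint), with priority
promoter > exonic > intronic. Using a point rather than the interval makes
the four categories an exact partition. "Promoter" is TSS ± 1 kb by
default; because promoter proximity is quoted both as "within 1 kb of
promoters" and "within 1 kb *upstream* of the TSS" in the literature, the
strand-aware upstream-only percentage is always computed alongside rather
than choosing one reading. Genes without exon annotation fall back to
gene-body = intronic.

## Expression: DE calling, candidate genes, enrichment

Differential expression between cell lines uses a per-gene Welch t-test on
log2 values with BH adjustment. This is a deliberate, documented stand-in
for an empirical-Bayes moderated t: moderation machinery is out of scope
here, and DE lists can be supplied externally as plain gene lists, making
the stand-in bypassable. The substitution has one important consequence at
n = 3 replicates: the Welch t has roughly 4 degrees of freedom, so even an
8-standard-deviation shift rarely clears a BH-adjusted 0.01 threshold
(median raw p ≈ 6e-4 against a step-up cutoff near 5e-4). An oracle
simulation of the planted-shift design (100 of 2,000 genes shifted 2 log2
units, σ = 0.25) recovers a median of 0 genes at adjusted p < 0.01 but
93–94 at raw p < 0.01 with a false-positive rate under 1%. The
candidate-gene filter — DE against *both* other lines but not between them —
therefore defaults to raw p < 0.01: the double-contrast requirement already
suppresses false candidates quadratically, and the FDR-controlled variant
remains available (`use_adjusted = TRUE`).

Enrichment of candidate DE genes near cell-line-specific peaks uses a 2×2
Fisher's exact test over the full gene universe (all genes in the
annotation; the universe choice is exposed, not hidden). The generic
`fisher_enrichment()` defaults to the standard two-sided
minimum-likelihood sum, but the candidate-gene stage asks a one-sided
question and uses `alternative = "greater"`: because candidates for line L
*exclude* genes DE between the other two lines, they are structurally
depleted near those lines' specific peaks, and a two-sided test would
report that depletion as cross-line "significance" even when there is no
enrichment anywhere. For the default, the reported odds ratio is the
*sample* odds ratio `ad/bc` (with a flagged 0.5 continuity add only when a
cell is zero), not the conditional MLE — printed odds ratios from other
software may use the other convention. Proximity percentages ("fraction of
peaks within ±20 kb of a regulated gene's TSS") are compared between peak
classes with an uncorrected 1-df chi-squared; a zero expected cell raises
an error recommending Fisher.

## The synthetic-data generator

Every analysis stage runs against generated data with the statistical
structure the methods assume. The generator is fully seeded: identical
configurations produce byte-identical files. Defaults
(`scenario_config()`):

| parameter | default | why |
|---|---|---|
| chromosomes | 2 × 5 Mb, i.i.d. uniform ACGT | desk-scale genome; minutes on one CPU |
| cell lines | MCF7, ZR751, MCF10A (last is ER-negative) | two ER-positive lines plus control |
| sites per factor/line | 1,000 (min spacing 2 kb) | enough peaks for stable fractions |
| co-binding rates | ER 4.8%, FOXA1 19.6%, both 4.8% of CTCF sites | the observed co-binding fractions (≈29% overall with chance overlap) |
| ER–FOXA1 share | 50% of non-CTCF ER sites carry FOXA1 | the pioneer-factor geometry: FOXA1 licenses ER binding, so ER∩FOXA1 sites exist away from CTCF |
| partner offset | uniform ±500 bp from the CTCF centre | co-binding is not summit-centred; partners sit within 1 kb |
| line-specific fraction | 13% | matches the observed specific-site share |
| replicate dropout | 5%, plus 50 private noise peaks/replicate | realistic replicate concordance |
| summit jitter / width | N(0, 20 bp); width N(400, 80) bp, floor 100 | MACS-like peak geometry |
| reads per library | 200,000; signal:background 4:1; N(summit, 100 bp) | clear pileups at desk scale |
| motif planting | 70% of sites, within ±50 bp of the summit | recoverable but not saturated |
| expression | 2,000 genes, 3 reps/line, σ = 0.25, ±2 log2 DE effect | microarray-like noise, 4-fold effects |
| DE placement | p = 0.3 near line-specific sites vs 0.05 background | the planted enrichment Table-1-style tests recover |

What it does **not** emulate: GC or mappability bias, fragment-length
effects, diploid genomes, correlated replicate noise, or any motif
degeneracy beyond the matrices' own column entropy. Passing tests on this
generator therefore demonstrate that the *statistics* behave as specified
under their own assumptions — calibration under the null, recovery of
planted structure — not that any biological conclusion transfers to a real
dataset.

## The pipeline and problem sizes

`run_pipeline()` chains simulate → consensus → co-binding → GSC → signal →
motifs → annotation → expression → report, writing TSV/JSON per stage plus
a manifest with MD5 digests and the seed. The pipeline defaults trade a
little Monte-Carlo resolution for turnaround: 2,000 GSC iterations
(p floor 5e-4) and 500 matrix permutations per PWM. Both are package
choices for the synthetic scale; the method defaults remain 10,000 and
1,000, and either can be raised in the configuration. A default run
completes in about a minute; the test suite's end-to-end determinism check
runs it twice and compares digests.

## Known limitations

* The GSC variant is validated by calibration, not by agreement with any
  particular historical implementation; its block length is a tuning
  parameter with the usual bias-variance trade-off (blocks too small leak
  structure into the null; too large waste randomization).
* The Gaussian-tail motif p-value is an approximation to a discrete null;
  for very sparse hit counts it can be anti-conservative, which is why the
  suite bounds — rather than assumes — its type-I behaviour.
* Welch-t DE calling without moderation is underpowered at 2–3 replicates
  relative to empirical-Bayes callers; the raw-p candidate filter
  compensates structurally (see above) but is not an FDR guarantee.
* Consensus and multi-line class counts depend mildly on the anchor
  replicate/line; both are recorded in outputs so the dependence is
  visible.
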