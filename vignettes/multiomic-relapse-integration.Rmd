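---
title: "Integrating chromatin loops, open chromatin and expression across disease timepoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating chromatin loops, open chromatin and expression across disease timepoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Longitudinal leukemia designs compare the same patients at diagnosis
and at relapse across three omic layers: long-range chromatin
contacts (proximity-ligation loop strengths, e.g. Omni-C processed to
per-loop continuous strengths), open chromatin (replicate ATAC-seq
peak calls), and gene expression (RNA-seq counts). The scientific
question is which regulatory contacts are specific to one timepoint,
whether those contacts coincide with timepoint-specific accessible
chromatin, which genes they plausibly regulate, and — for genes that
go *up* at relapse while *losing* a diagnosis-specific contact —
whether the lost distal partner carried the repressive mark H3K27me3,
i.e. whether upregulation is explained by loss of a silencer or
poised-enhancer contact.

`triomics` implements that comparison as a tested pipeline with a
typical 2-vs-2 design (two diagnosis and two relapse samples), and
ships a synthetic-data generator with planted ground truth so every
stage can be validated end to end without any external download.

# Differential loops and differential expression

Both count-like layers share one statistical engine.

**Matrix construction.** Each row is a chromatin loop (a pair of
anchors, canonically ordered) or a gene; each column a sample. Loop
strengths are continuous and nonnegative and are accepted as-is —
"library size" is the column sum. A loop absent from one sample's
file simply has strength 0 there; no presence filter is applied,
because the variance ranking already promotes informative rows.

**Normalization.** Between-sample composition bias is corrected with
the trimmed mean of M-values (TMM): the reference sample is the one
whose upper-quartile/library-size ratio is closest to the mean such
ratio; for every sample the log2 ratios against the reference
(M-values) are doubly trimmed (30% of M, 5% of A, both tails),
combined with inverse delta-method-variance weights, and the
resulting factors are rescaled to geometric mean 1. Values are then
placed on a log2 counts-per-million scale with a prior count of 0.5
(which keeps zeros finite). Note one subtlety verified by the test
suite: because the precision weights depend on sequencing depth, TMM
factors are *exactly* invariant to per-sample depth only up to the
weighting, so factors can move in the third decimal when a column is
rescaled — the published estimator behaves identically.

**Feature selection (loops only).** The `n_top` most variable loops
by row standard deviation (sample SD, denominator $n-1$, ties broken
by input order) are tested; 100,000 is the full-scale default, and a
value larger than the number of loops tests everything. Multiple
testing is corrected *within the tested subset only*.

**Testing.** Per feature, a two-group fit gives
$\log FC = \bar{x}_{relapse} - \bar{x}_{diagnosis}$ and a pooled
residual variance $s^2$ with $n-2$ degrees of freedom. Residual
variances are shrunk by empirical Bayes toward a scaled-F prior
fitted by moments on $\log s^2$; the prior degrees of freedom $d_0$
come from inverting the trigamma function with a monotone Newton
iteration, and

$$s^2_{post} = \frac{d_0 s_0^2 + d_{res} s^2}{d_0 + d_{res}},
\qquad t = \frac{\log FC}{\sqrt{s^2_{post}(1/n_1 + 1/n_2)}}$$

is referred to a t distribution with $d_0 + d_{res}$ degrees of
freedom. When the spread of $\log s^2$ does not exceed chi-square
sampling spread, $d_0 = \infty$ and every variance shrinks fully to
the mean variance. A variance floor of `1e-8` guards exact
duplicates (synthetic data can produce identical columns). p-values
are adjusted by Benjamini–Hochberg step-up with monotonicity
enforcement.

For RNA-seq a simplified mean–variance weighting is on by default
(`weight_trend = TRUE`): a running median of the quarter-root
variance against average log2 abundance defines per-gene weights
$w_g = \mathrm{trend}^{-4}$ that standardize variances before
shrinkage; loop strengths do not show the strong count-driven
mean–variance trend, so the flag defaults off there. This mirrors the
common practice of applying precision weights to RNA counts but a
plain moderated test to derived continuous signals.

**Calls.** Significant loops (`p_adj < 0.1`) are split by the sign of
the fold change into relapse-specific (positive) and
diagnosis-specific (negative); no fold-change cutoff is applied to
loops because none is part of the design. DE genes additionally
require `|log2FC| > 1` (strict inequalities on both thresholds).

# State-specific open chromatin

Reproducibility is *replicate-anchored*: the "common diagnosis" set
is the peaks of the first diagnosis replicate having at least one
overlapping peak (any overlap, half-open coordinates) in the second;
same for relapse. This keeps peak boundaries exactly as called
rather than fragmenting them into base-pair intersections. The
choice of reference replicate is the first-listed sample and is
configurable. State-specific sets are whole-peak set differences
(`diagnosis_specific = common_diagnosis` minus anything overlapping
`common_relapse`, and vice versa), and the "shared" set — regions
open at both timepoints — is reported in diagnosis-side coordinates
(a side must be chosen; it is recorded in the output metadata).
These operations satisfy, and the tests assert, the identities
$|common_d| = |d\text{-specific}| + |common_d \cap common_r|$ and
idempotence under re-application.

# Integration

1. **Accessible anchors.** Anchors of state-specific loops
   (deduplicated by exact coordinates — overlapping-but-unequal
   anchors stay distinct) are intersected with the same state's
   specific peaks; any overlap counts.
2. **Gene assignment.** A gene is linked to an accessible anchor when
   the anchor extended by 20 kb on both sides overlaps the gene body
   by at least one base. 20 kb is the distance within which a
   regulatory contact is considered assignable to a promoter.
3. **Promoter vs distal end.** The linked (accessible) anchor is the
   promoter-side anchor of a record; the loop's other end is the
   distal anchor — the candidate enhancer or silencer. If both ends
   of a loop link the same gene, the end farther from the gene body
   is distal. Records where both ends coincide are dropped.
4. **Enrichment against random gene sets.** The median log2 fold
   change of the linked upregulated genes is compared with 10 random
   size-matched gene sets (the mean is available behind a flag; the
   median is robust for the small sets involved). Random sets are
   drawn without replacement from the expressed-gene universe
   (counts-per-million > 1 in at least two samples) *excluding* the
   observed set, to avoid self-inflation. The default universe is
   genome-wide expressed genes; sampling from upregulated genes only
   is available as an option, since both conventions are defensible.
   The empirical p-value uses the add-one rule with ties counting as
   exceedances: $p = (\#\{null \ge obs\} + 1)/(n_{random}+1)$.
5. **Silencer-loss permutation test.** Candidates are
   diagnosis-specific records whose gene is upregulated at relapse —
   *upregulated meaning positive log2 fold change*, not the
   significance-thresholded DE call. The two notions differ
   materially: a gene can lose a silencer contact and rise
   meaningfully without clearing a genome-wide FDR bar in a 2-vs-2
   design, and the silencer-loss hypothesis concerns the direction
   of change. (The strict DE-call variant can be recovered by
   filtering records on `de_call == "up"`.) The observed statistic
   is the fraction of candidate genes whose distal anchor overlaps
   at least one H3K27me3 interval. Each of the 10,000 null
   replicates re-places every candidate distal anchor uniformly on
   its own chromosome with identical width — preserving interval
   size and chromosome composition, which is one defensible
   exchangeability choice among several — and the p-value is again
   add-one with ties as exceedances, so it is bounded below by
   $1/(n_{perm}+1)$. With zero exceedances at $n_{perm} = 10{,}000$
   the estimator equals $1/10001$, which the report prints truncated
   (not rounded) to three significant figures: $9.99\times10^{-5}$.
6. **Tri-omic genes.** Genes that are DE-significant *and* linked to
   a state's accessible anchors (which already requires both the
   loop and the peak layer) are reported as consistent across all
   three omics.

# The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, for a 2-diagnosis / 2-relapse design:

- **Loops**: log-normal baseline strengths (meanlog $\log 10$, sdlog
  1), multiplicative log-normal noise (natural-log SD 0.3), per-sample
  depth factors drawn from $[0.7, 1.4]$ to exercise TMM, and 5% of
  loops multiplied by $2^{\pm 2}$ in their favored group.
- **Peaks**: 500 bp planted peaks inside every differential-loop
  anchor, present in both replicates of their state with probability
  0.9 (otherwise in one replicate, chosen at random); 4,000
  background peaks present in all four samples; 500 per-sample noise
  peaks.
- **Genes**: negative-binomial counts with common dispersion 0.1 and
  log-normal means (meanlog $\log 100$, sdlog 1, floor 2); 200 DE
  genes at $|\log_2 FC| = 2$, half up, half down.
- **Wiring**: ten upregulated genes sit immediately downstream of the
  promoter anchors of diagnosis-specific loops whose distal anchors
  are covered by H3K27me3 (the planted silencer-loss genes); ten more
  upregulated genes are wired the same way to relapse-specific loops.
  Background H3K27me3 covers ~1% of the genome so the permutation
  null is small but nonzero.
- **Geometry**: planted loops occupy regular non-overlapping slots;
  promoter anchors in the first 40% of each chromosome, distal
  anchors 40% of a chromosome length downstream (guaranteeing the
  100 kb promoter–distal separation); unwired genes, background and
  noise peaks live in the last 20% so random placement cannot
  contaminate planted truth. An impossible layout (too many planted
  elements) raises a geometry error rather than silently
  overlapping.

The default desk-scale configuration (`default_desk_config()`): two
10 Mb chromosomes, 20,000 loops, 5,000 genes, seed 1337; the full
pipeline runs in well under a minute on one CPU at this scale, which
is also the problem size the test suite and the acceptance script
use.

**What the generator does not emulate** — and hence what passing
tests do *not* show about real data: Hi-C distance decay and
domain/compartment structure, peak-width and signal heterogeneity,
gene-density variation, GC and mappability bias, patient-to-patient
heterogeneity (the real design's dominant variance axis), and any
read-level artifact. The generator validates the statistical engine
and the integration plumbing, not the upstream callers.

# Numerical and design choices

- Coordinates are BED-convention 0-based half-open in all files and
  data frames; overlap queries convert to 1-based closed GRanges
  internally at a single boundary. Abutting intervals do not
  overlap. Chromosome names match exactly (no "chr" aliasing); a
  validation warning fires when two inputs share no chromosome
  names.
- "Normalized with edgeR" in this field means TMM in practice; TMM
  with the published defaults (30%/5% trims, upper-quartile
  reference) is the adopted normalization, and log2 CPM with prior
  0.5 the adopted transform.
- The trigamma inversion runs Newton on $1/\text{trigamma}$ starting
  at $0.5 + 1/y$, with closed-form guards for extreme arguments;
  convergence tolerance $10^{-10}$ relative.
- Fewer than 10 positive residual variances: the prior cannot be
  fitted, so $d_0 = \infty$ and full shrinkage to the mean variance.
  All-zero variances are an error instructing use of the variance
  floor.
- Master seed 1337 by default; every stochastic stage derives an
  independent substream (recorded in its output), so reports are
  byte-identical across reruns with the same configuration.
- Ties: top-variable selection is stable in input order; both
  permutation procedures count ties as exceedances (conservative).

# Known limitations

- The 2-vs-2 design has little power for per-feature dispersion
  differences; the empirical-Bayes moderation assumes a common
  variance prior across features.
- Whether precision weights should also apply to loop matrices is
  genuinely open; the package defaults to no weights for loops and
  weights for RNA, both switchable.
- The permutation null for silencer loss preserves width and
  chromosome but not local chromatin context; enrichment against a
  context-matched null (e.g. distance-to-TSS matched) would be
  stricter.
- Peak-level (presence/absence) state specificity ignores
  quantitative accessibility differences; a count-based differential
  accessibility analysis is out of scope by design.
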