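---
title: "Multi-factor cistrome integration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-factor cistrome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistrio)
```

# The analysis

An anchor transcription factor (in the motivating system, ERα in MCF-7
breast cancer cells) binds tens of thousands of genomic sites, almost
always in the company of other factors. This package implements the
integration steps that turn a collection of peak sets and tag tracks into
statements about that company: which candidate cofactors overlap the
anchor cistrome most, how sites distribute over the 2^k combinations of k
cofactors, whether combinatorial occupancy grades binding strength, where
super-enhancers concentrate among co-bound regions, what a cofactor
knockdown does to anchor binding and chromatin accessibility, and whether
the cofactors' expression stratifies patient outcome.

All interval arithmetic runs on `GRanges`; BED files are 0-based
half-open at the boundary and converted on the way in. Chromosome names
match by literal string equality — "chr1" and "1" are different
chromosomes unless the caller harmonizes them first.

# Models and statistics

## Overlap coefficient

Two denominators for "fraction of overlap" are in circulation, and they
answer different questions, so `overlapScreen()` always reports both:

* `coefficient_anchor = |{a ∈ A : a overlaps C}| / |A|` — the fraction of
  the anchor cistrome that a candidate explains; the default ranking key.
* `coefficient_merged` — merged-union peaks containing contributions from
  both sets, divided by the merged-union peak count; symmetric-ish and
  always ≤ the anchor variant when |A| ≤ |A ∪ C|.

The overlap predicate is ≥ `min_bp` shared bases (default 1 bp). Both
sets are self-merged before counting so fragmented peak calls do not
inflate counts.

## Binned density and its unit

`binnedDensity()` extends every site to a fixed flank (default 2,000 bp)
on each side of its center — the floor midpoint for even-length
intervals — and divides the window into `2·flank/bin_width` bins (default
40 × 100 bp). Bins are half-open; a tag exactly on a boundary belongs to
the bin whose left edge it sits on. Counts are scaled by
`10⁷ / total_mapped`, giving reads per 10 million mapped reads per bin.
Two consequences used as test invariants: doubling every tag together
with the library size changes nothing, and bin sums over a site-spanning
window equal `siteSignal()` on that window (tag conservation). Windows
that would run below position 0 are clipped with zero fill.

A "tag" is one bp per read (5′ position, optionally shifted, or the read
midpoint) — the package does not model fragment length.

## S-codes

`classifyCombinations()` gives each anchor site a binary code over the
caller's ordered factor list; bit i is set iff the site shares ≥ `min_bp`
bases with factor i (Boolean membership — two overlapping intervals of
one factor still set the bit once). Codes partition the anchor set, so
coverage by cardinality (fraction bound by exactly 0..k factors) sums
to 1. The shipped defaults use the order (GATA3, NR2F2, FOXA1), so "110"
reads "GATA3 and NR2F2 but not FOXA1".

For shared-program analysis, `nmfBinding()` factorizes the nonnegative
site-by-factor signal matrix by multiplicative Frobenius updates. The
rank, input normalization and initialization are explicit parameters
(seeded nonnegative-random init); the error trace is returned because
non-increase per sweep is the method's defining property. Multiplicative
updates can stall in flat regions, so `nStart` random restarts are
available; small dense problems (a few factor columns) are the intended
regime.

## Super-enhancers

`stitchRegions()` merges enhancer constituents within 12,500 bp (the
stitching distance of the ROSE method; exposed as a parameter), with an
optional ±2,000 bp TSS-exclusion window applied to constituents before
stitching. Region signal is the sum of constituent `siteSignal()` values
— constituent accounting, not the stitched span — with optional control
subtraction floored at 0.

`rankAndCut()` sorts regions ascending by signal, scales rank and signal
to [0, 1], and places the cutoff where a line of slope 1 touches the
scaled curve from below — the index minimizing `scaled_signal −
scaled_rank`, which on a convex increasing curve is exactly the
tangent-slope-1 point (on y = x² that is rank 0.5, signal 0.25, the
closed-form case frozen into the tests). An earlier first-crossing scan
of the discrete slopes proved fragile: one isolated low-signal region at
the bottom of the curve creates a single steep step there and flags
nearly everything; the tangent-touch minimization is equivalent on clean
curves and immune to that failure. Flags are invariant under positive
affine rescaling because of the min-max scaling. An exactly linear curve
warns and flags nothing; all-equal signals are an error — there is no
elbow.

`assignNearestGene()` measures region-center-to-TSS distance and breaks
ties lexicographically by gene name, so results are deterministic.

## Knockdown classification

`classifyBindingChange()` computes per-site
`log2((kd + pc)/(ctrl + pc))` with pseudocount 0.5 and classifies at a
symmetric 1.5-fold threshold: weaker (≤ −log2 1.5), stronger (≥ +log2
1.5), else unchanged. Neither the threshold nor the pseudocount is
canonical — both are parameters stamped into outputs. The construction
guarantees two properties the tests enforce: class fractions sum to 1 and
are monotone in the threshold, and swapping the two tracks swaps weaker
and stronger exactly. `peaksetDiff()` counts lost/shared/gained peaks on
self-merged sets; `stratifiedProfiles()` gives per-class mean profiles
with heatmap rows ordered by descending control signal.

## E-codes and survival

`encodeExpression()` binarizes each patient per gene against the cohort
arithmetic mean; strictly greater codes 1, a value exactly at the mean
codes 0. Code groups below a minimum size (default 5) are flagged for
exclusion — mirroring the practice of dropping groups too small to
estimate — and the exclusions are always reported. Kaplan–Meier curves
and the log-rank test are delegated to the survival package
(`survfit`/`survdiff`) behind `kmEstimate()`/`logrankTest()`; a
permutation-mode p-value is available for small samples. The log-rank
test is a documented default, not the only defensible choice.

# The synthetic-data generator

Real multi-factor cistrome studies rest on external sequencing data that
a desk-scale package cannot ship, so `simConfig()` +
`simulateCistromes()`/`simulateTags()`/`simulateSeSignals()`/
`simulateCohort()` generate inputs with the structure those analyses
assume, returning the planted truth so every stage is checked by
parameter recovery.

* **Sites and codes.** Latent sites are placed uniformly, ≥ 4,000 bp
  apart, on a 240-Mb three-chromosome toy genome; each draws a co-binding
  code. The default design plants 25% triple-bound, 36% double, 24%
  single, 15% unbound (equal split within a cardinality), so the trio
  covers 85% of anchor sites and each factor's marginal is 0.57. Factor
  peaks get ~N(300, 50²) bp widths (floored at 50) and N(0, 30²) bp
  center jitter — separations are so much larger than widths that code
  recovery is limited only by sampling noise.
* **Tags.** Background tags are Poisson (10⁻⁵/bp); each site adds
  Poisson(multiplier × 60) tags from a truncated-normal kernel (sd = a
  quarter of the site width). Anchor enrichment grows with co-binding
  cardinality (multipliers 0.5 / 1 / 2 / 4 for 0–3 factors), encoding the
  claim that sites bound by more factors bind the anchor more strongly.
  By default `total_mapped` is the realized tag count; a nominal common
  depth can be passed instead — the knockdown stage uses 10⁷ for both
  conditions because attenuating 60% of sites 4× removes nearly half of
  all tags, and realized-count normalization would convert that library
  shrinkage into spurious "stronger" calls at untouched sites. Equal
  sequencing depth across conditions is the implicit experimental design.
* **Enhancer intensities.** A 95/5 mixture: gamma(5, 2) body and
  Pareto(shape 2.5, scale 150) tail. The scale separates tail from body
  cleanly, which is what "a small subset of regions with exceptionally
  high signal" means operationally; the tangent cutoff then recovers
  ≥ 90% of the planted tail while flagging 2–8% of regions.
* **Knockdown.** Anchor tags attenuate 4× at sites whose code has the
  NR2F2 bit. The knockdown experiment's co-binding design sets that
  bit's marginal to exactly 0.60 (probabilities .25/.12/.13/.12/.10/
  .07/.06/.15 over 111…000), the stated study condition for the recovery
  checks.
* **Cohort.** Per-gene expression is gaussian around 9 (high bit) or 2
  (low bit) with sd 1.25, truncated at 0 — a separation chosen so the
  mean-binarized E-code reproduces the planted code for ≥ 95% of
  patients, which is the generator's stated contract. Event times are
  exponential with hazard 0.05 × multiplier; by default codes with at
  most one high bit carry the hazard ratio (3), encoding "low expression
  of the trio worsens outcome". Censoring is independent exponential
  (rate 0.03).

What the generator does **not** emulate: GC and mappability bias,
fragment-length effects, copy-number variation, peak-calling artifacts,
correlated backgrounds between tracks, non-exponential survival, or
covariate structure in the cohort. Passing recovery tests therefore shows
the analysis machinery is correct and calibrated on its stated model, not
that any biological conclusion transfers to a particular dataset.

# Problem sizes and numerical choices

The test suite runs the recovery checks at the sizes the analyses are
designed for: 20,000 latent sites for combination recovery, 10,000 for
the knockdown split, 30,000 for peak-loss recovery, 6,000 regions for the
super-enhancer mixture, 400 patients (with 500 null and 200 powered
replicates) for survival calibration, and 200 random instances up to
1,000×1,000 intervals against the brute-force overlap oracle; the demo
pipeline and smaller property tests use 300–4,000 sites. Determinism is
end-to-end: one seed drives every stage, stage seeds are fixed offsets of
it, and the pipeline's `summary.txt` is byte-identical across reruns
(timestamps live only in `manifest.json`).

Tie-breaks are deterministic everywhere: screen rows by factor label,
nearest genes lexicographically, sites by (chromosome, start) with
lexicographically ordered chromosome names. Degenerate inputs fail loudly
(empty anchor, zero-variance gene or signal vector, all-equal signals,
zero events) rather than returning NaN.

# Known limitations

* The weaker/unchanged/stronger thresholds, the overlap `min_bp`, the
  NMF rank and the minimum survival-group size are documented defaults,
  not values with an external ground truth; published percentage splits
  obtained with unstated thresholds cannot be reproduced exactly, only
  the classification framework.
* BAM and bigWig inputs are out of scope; tags arrive as BED positions
  (or intervals reduced to one position per read).
* The merged-denominator overlap coefficient can, in edge cases where
  peaks merely touch (zero shared bases), count a merged peak whose
  constituents do not overlap at `min_bp = 1`.
* `assignNearestGene()` is O(regions × genes) per chromosome — fine for
  hundreds of regions, not for genome-wide queries against full gene
  annotations.
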