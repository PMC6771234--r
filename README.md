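# cistrio

Integration of multiple transcription-factor cistromes around an anchor
factor, written for regulatory-genomics analyses of the kind done in
ER-positive breast cancer cell lines: which cofactors co-occupy the
estrogen receptor's binding sites (ERBS), how combinatorial co-binding
relates to binding strength and chromatin accessibility, where
super-enhancers sit among co-bound regions, what a cofactor knockdown does
to anchor binding, and whether the cofactor trio's expression stratifies
patient survival.

## What it computes

* **Cofactor overlap screen** — for an anchor peak set A and candidate set
  C, the overlap coefficient in both conventions found in practice:
  `|{a in A : a overlaps C}| / |A|` (anchor denominator) and the fraction
  of merged-union peaks containing contributions from both sets (merged
  denominator). Overlap means ≥ `min_bp` shared bases (default 1) on
  0-based half-open BED intervals.
* **Binned read density** — each site extended ±2 kb from its center, the
  4-kb window cut into 40 bins of 100 bp, and tag counts normalized to
  reads per 10 million mapped reads per bin (`10*rpm/bp`):
  `value = count · 10⁷ / total_mapped`.
* **Combinatorial co-binding (S-codes)** — each anchor site gets a binary
  code over an ordered factor list (GATA3, NR2F2, FOXA1 in the shipped
  defaults); `S110` = bound by GATA3 and NR2F2. Codes partition the anchor
  set; coverage by cardinality summarizes how much of the cistrome the
  trio explains. An NMF of the site-by-factor signal matrix
  (multiplicative Frobenius updates) exposes shared binding programs.
* **Super-enhancers** — ROSE-style stitch-and-rank: constituents within
  12.5 kb are stitched (optional ±2 kb TSS exclusion), regions ranked by
  summed normalized signal, rank and signal scaled to [0, 1], and the
  cutoff placed where a slope-1 line is tangent to the signal-vs-rank
  curve from below; regions above it are super-enhancers. Nearest-TSS
  proximity assigns each super-enhancer a gene.
* **Knockdown perturbation** — per-site `log2((kd + 0.5) / (ctrl + 0.5))`
  classifies sites as weaker / unchanged / stronger at a symmetric
  1.5-fold threshold; peak-set differencing quantifies e.g. ATAC peak loss
  between conditions.
* **Expression codes and survival (E-codes)** — patients are binarized per
  gene against the cohort mean expression (strictly greater = 1), grouped
  by code (small groups excluded), and compared by Kaplan–Meier curves and
  the log-rank test.

A seeded synthetic-cistrome generator (`simConfig()`, `simulateCistromes()`,
`simulateTags()`, `simulateSeSignals()`, `simulateCohort()`) produces all
inputs with planted ground truth, so every stage is testable by parameter
recovery without external data.

## Worked example

```r
library(cistrio)
res <- runPipeline(simConfig(seed = 1), outDir = "demo_out")
readLines(file.path("demo_out", "summary.txt"))
```

Selected lines of `summary.txt` from that exact run (seed 1, 20,000 latent
sites, 400 patients):

```
overlap_coefficient_anchor  NR2F2   0.5704
coverage_cardinality_3      0.2511
coverage_cardinality_2      0.3589
coverage_cardinality_1      0.2379
coverage_any_factor         0.8479
prepost_r_squared           0.956543
n_stitched_regions          4101
n_super_enhancers           224
super_enhancer_genes_unique 217
binding_change_weaker       0.6068
binding_change_unchanged    0.3873
binding_change_stronger     0.0059
atac_lost_fraction          0.6816
logrank_p                   1.90723e-16
```

Reading: 57% of anchor sites are co-bound by NR2F2 and the trio covers 85%
of the anchor cistrome (25% by all three, 36% by two, 24% by one), matching
the generator's planted design; replicate signal tracks with no condition
effect correlate at R² ≈ 0.96; 224 of 4,101 stitched co-bound regions carry
exceptionally high enhancer-mark signal and map to 217 unique nearest
genes; knocking the cofactor down makes 61% of anchor sites weaker and
costs 68% of accessibility peaks; and the 3-gene expression code separates
patient survival at p ≈ 2×10⁻¹⁶.

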