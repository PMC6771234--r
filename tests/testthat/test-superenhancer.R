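test_that("stitchRegions merges constituents within the stitching distance", {
  near <- GRanges("chr1", IRanges(c(10001, 15501), width = 500))  # 5 kb apart
  one <- stitchRegions(near)
  expect_length(one, 1L)
  expect_equal(mcols(one)$constituentCount, 2L)

  far <- GRanges("chr1", IRanges(c(10001, 30501), width = 500))  # 20 kb apart
  expect_length(stitchRegions(far), 2L)
})

test_that("stitching is idempotent, order-insensitive and coverage-preserving", {
  set.seed(70)
  for (rep in 1:5) {
    sites <- rGR(120, maxStart = 500000, maxWidth = 800)
    st <- stitchRegions(sites)
    expect_equal(granges(stitchRegions(st)), granges(st))
    shuffled <- sites[sample(length(sites))]
    expect_equal(granges(stitchRegions(shuffled)), granges(st))
    expect_gte(coveredBp(st), coveredBp(sites))
    # every constituent lands in exactly one stitched region
    expect_equal(sum(mcols(st)$constituentCount), length(sites))
    expect_lte(length(st), length(mergeSelf(sites)))
  }
})

test_that("promoter-proximal constituents are excluded when a TSS table is given", {
  sites <- GRanges("chr1", IRanges(c(10001, 100001), width = 400))
  tss <- data.frame(gene = "G1", chrom = "chr1", pos = 10100, strand = "+")
  expect_message(st <- stitchRegions(sites, tss = tss, tssExclusion = 2000),
                 "excluded")
  expect_length(st, 1L)
  expect_equal(start(st), 100001L)
})

test_that("rankAndCut places the slope-1 tangent cutoff of y = x^2 at rank 0.5", {
  n <- 101
  x <- (seq_len(n) - 1) / (n - 1)
  regions <- GRanges("chr1", IRanges(seq(1, by = 1000, length.out = n), width = 100))
  mcols(regions)$signal <- x^2
  res <- rankAndCut(regions)
  expect_equal(cutoffSignal(res), 0.25)       # scaled signal at scaled rank 0.5
  expect_equal(nSuper(res), 50L)              # upper half of the rank curve
  expect_true(all(mcols(superRegions(res))$signal > 0.25))
})

test_that("rankAndCut handles degenerate curves", {
  regions <- GRanges("chr1", IRanges(seq(1, by = 1000, length.out = 50), width = 100))
  mcols(regions)$signal <- seq(0, 1, length.out = 50)  # perfectly linear
  expect_warning(res <- rankAndCut(regions), "slope")
  expect_equal(nSuper(res), 0L)

  mcols(regions)$signal <- rep(2, 50)
  expect_error(rankAndCut(regions), "equal")
  expect_error(rankAndCut(regions[1:2]), "3")
  expect_error(rankAndCut(granges(regions)), "signal")
})

test_that("super-enhancer flags are invariant under positive affine rescaling", {
  set.seed(71)
  regions <- GRanges("chr1", IRanges(seq(1, by = 5000, length.out = 400), width = 200))
  sig <- simulateSeSignals(simConfig(seed = 5), 400)$signal
  mcols(regions)$signal <- sig
  base <- rankAndCut(regions)
  mcols(regions)$signal <- 3.7 * sig + 11
  scaled <- rankAndCut(regions)
  expect_equal(mcols(base@regions)$isSuper, mcols(scaled@regions)$isSuper)
  expect_equal(nSuper(base), nSuper(scaled))
})

test_that("the Pareto tail of the intensity mixture is recovered as super-enhancers", {
  cfg <- simConfig(seed = 12)
  nFlag <- integer(3)
  for (s in 1:3) {
    sim <- simulateSeSignals(cfg, 2000, seed = s)
    regions <- GRanges("chr1", IRanges(seq(1, by = 5000, length.out = 2000),
                                       width = 200))
    mcols(regions)$signal <- sim$signal
    res <- rankAndCut(regions)
    flagged <- mcols(res@regions)$isSuper[order(order(sim$signal))]
    expect_gte(mean(flagged[sim$isTail]), 0.9)  # planted-tail recall
    nFlag[s] <- nSuper(res)
  }
  expect_true(all(abs(nFlag - mean(nFlag)) <= 0.1 * mean(nFlag) + 2))
})

test_that("assignNearestGene matches an exhaustive oracle with lexicographic ties", {
  regions <- GRanges("chr1", IRanges(c(9951, 10051), width = 100))  # centers 10000, 10100
  tss <- data.frame(gene = c("B", "A", "C"), chrom = "chr1",
                    pos = c(10000, 10000, 26000), strand = "+")
  res <- assignNearestGene(regions, tss)
  expect_equal(res$assignments$gene, c("A", "A"))  # tie at 0 -> lexicographic
  expect_equal(res$assignments$distance, c(0, 100))
  expect_equal(res$uniqueGenes, 1L)  # two regions de-duplicate to one gene

  set.seed(72)
  regions <- rGR(60, chroms = c("chr1", "chr2"), maxStart = 100000)
  tss <- data.frame(gene = paste0("G", 1:40),
                    chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                    pos = sample.int(100000, 40), strand = "+")
  res <- assignNearestGene(regions, tss)
  centers <- floor((start(regions) - 1 + end(regions)) / 2)
  for (i in seq_along(regions)) {
    onChrom <- tss[tss$chrom == as.character(seqnames(regions))[i], ]
    d <- abs(onChrom$pos - centers[i])
    expect_equal(res$assignments$distance[i], min(d))
    expect_equal(res$assignments$gene[i], min(onChrom$gene[d == min(d)]))
  }
})

test_that("regions on chromosomes without TSS entries are left unassigned", {
  regions <- GRanges(c("chr1", "chrX"), IRanges(c(1001, 1001), width = 100))
  tss <- data.frame(gene = "G1", chrom = "chr1", pos = 500, strand = "+")
  expect_message(res <- assignNearestGene(regions, tss), "unassigned")
  expect_true(is.na(res$assignments$gene[2]))
  expect_error(assignNearestGene(regions, tss[0, ]), "empty")
})
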