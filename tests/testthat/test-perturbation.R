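test_that("classifyBindingChange applies symmetric log2 fold-change thresholds", {
  sites <- GRanges("chr1", IRanges(c(1001, 5001, 9001), width = 100))
  # per-site counts: ctrl (10, 5, 2), kd (2, 5, 10); totalMapped 1e7 -> signal = count
  ctrl <- exactTrack(rep("chr1", 17),
                     c(rep(1050, 10), rep(5050, 5), rep(9050, 2)))
  kd <- exactTrack(rep("chr1", 17),
                   c(rep(1050, 2), rep(5050, 5), rep(9050, 10)))
  bc <- classifyBindingChange(sites, ctrl, kd)
  expect_equal(siteClasses(bc), c("weaker", "unchanged", "stronger"))
  expect_equal(sum(classFractions(bc)), 1)
  expect_error(classifyBindingChange(sites, ctrl, kd, fcThreshold = 1), "> 1")

  identical_bc <- classifyBindingChange(sites, ctrl, ctrl)
  expect_equal(unname(classFractions(identical_bc)["unchanged"]), 1)
})

test_that("swapping control and knockdown exactly swaps weaker and stronger", {
  cfg <- simConfig(seed = 13, nSites = 1500, comboProbs = c(
    "111" = 0.25, "110" = 0.12, "011" = 0.13, "101" = 0.12,
    "010" = 0.10, "100" = 0.07, "001" = 0.06, "000" = 0.15))
  sim <- simulateCistromes(cfg)
  targeted <- substr(sim$truth$code, 2, 2) == "1"
  ctrl <- simulateTags(cfg, sim$anchor, rep(1, 1500), seed = 1, totalMapped = 1e7)
  kd <- simulateTags(cfg, sim$anchor, ifelse(targeted, 0.25, 1), seed = 2,
                     totalMapped = 1e7)
  fwd <- classifyBindingChange(sim$anchor, ctrl, kd)
  rev <- classifyBindingChange(sim$anchor, kd, ctrl)
  expect_equal(unname(classFractions(fwd)["weaker"]),
               unname(classFractions(rev)["stronger"]))
  expect_equal(unname(classFractions(fwd)["stronger"]),
               unname(classFractions(rev)["weaker"]))
  expect_equal(bc <- siteClasses(fwd) == "unchanged",
               siteClasses(rev) == "unchanged")
})

test_that("weaker and stronger fractions are non-increasing in the threshold", {
  cfg <- simConfig(seed = 14, nSites = 800)
  sim <- simulateCistromes(cfg)
  ctrl <- simulateTags(cfg, sim$anchor, rep(1, 800), seed = 3, totalMapped = 1e7)
  kd <- simulateTags(cfg, sim$anchor, runif(800, 0.2, 2), seed = 4,
                     totalMapped = 1e7)
  fr <- vapply(c(1.2, 1.5, 2, 3), function(t) {
    f <- classFractions(classifyBindingChange(sim$anchor, ctrl, kd, fcThreshold = t))
    c(f[["weaker"]], f[["stronger"]])
  }, numeric(2))
  expect_true(all(diff(fr[1, ]) <= 0))
  expect_true(all(diff(fr[2, ]) <= 0))
})

test_that("peaksetDiff counts match a brute-force membership oracle", {
  a <- mergeSelf(rGR(100, maxStart = 50000))
  same <- peaksetDiff(a, a)
  expect_equal(same@lostFraction, 0)
  expect_equal(same@nShared, length(a))

  b <- GenomicRanges::shift(a, 10^6)
  expect_equal(peaksetDiff(a, b)@lostFraction, 1)

  set.seed(73)
  for (rep in 1:5) {
    x <- rGR(150, maxStart = 20000)
    y <- rGR(120, maxStart = 20000)
    d <- peaksetDiff(x, y)
    xM <- mergeSelf(x); yM <- mergeSelf(y)
    shared <- bruteCountOverlapping(xM, yM)
    expect_equal(d@nShared, shared)
    expect_equal(d@nOnlyA, length(xM) - shared)
    expect_equal(d@nOnlyB, length(yM) - bruteCountOverlapping(yM, xM))
    expect_equal(d@nOnlyA + d@nShared, length(xM))
  }
})

test_that("stratifiedProfiles reproduces whole-set profiles for single-class tables", {
  cfg <- simConfig(seed = 15, nSites = 300)
  sim <- simulateCistromes(cfg)
  trk <- simulateTags(cfg, sim$anchor, rep(1, 300), seed = 5, totalMapped = 1e7)
  bc <- classifyBindingChange(sim$anchor, trk, trk)  # all unchanged
  w <- testthat::capture_warnings(prof <- stratifiedProfiles(bc, list(anchor = trk)))
  expect_true(any(grepl("empty", w)))  # weaker and stronger classes are empty
  expect_named(prof, "unchanged")
  expect_equal(prof$unchanged$profiles$anchor,
               meanProfile(binnedDensity(sim$anchor, trk)))
  expect_equal(prof$unchanged$n, 300L)
  # heatmap order is descending control signal
  sc <- bc@signalControl[prof$unchanged$order]
  expect_true(all(diff(sc) <= 0))
})

test_that("knockdown lowers accessibility signal at weaker sites but not stronger ones", {
  cfg <- simConfig(seed = 16, nSites = 2000, comboProbs = c(
    "111" = 0.25, "110" = 0.12, "011" = 0.13, "101" = 0.12,
    "010" = 0.10, "100" = 0.07, "001" = 0.06, "000" = 0.15))
  sim <- simulateCistromes(cfg)
  targeted <- substr(sim$truth$code, 2, 2) == "1"
  atacMult <- ifelse(targeted, 0.25, 1)
  erCtrl <- simulateTags(cfg, sim$anchor, rep(1, 2000), seed = 6, totalMapped = 1e7)
  erKd <- simulateTags(cfg, sim$anchor, atacMult, seed = 7, totalMapped = 1e7)
  atacCtrl <- simulateTags(cfg, sim$anchor, rep(1, 2000), seed = 8, totalMapped = 1e7)
  atacKd <- simulateTags(cfg, sim$anchor, atacMult, seed = 9, totalMapped = 1e7)
  bc <- classifyBindingChange(sim$anchor, erCtrl, erKd)
  prof <- suppressWarnings(
    stratifiedProfiles(bc, list(atac_ctrl = atacCtrl, atac_kd = atacKd)))
  central <- function(v) mean(v[20:21])
  expect_lt(central(prof$weaker$profiles$atac_kd),
            central(prof$weaker$profiles$atac_ctrl))
  if (!is.null(prof$stronger))
    expect_gte(central(prof$stronger$profiles$atac_kd),
               central(prof$stronger$profiles$atac_ctrl) * 0.8)
})
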