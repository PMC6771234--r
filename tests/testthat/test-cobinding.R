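test_that("classifyCombinations assigns S-codes in the caller's factor order", {
  anchor <- GRanges("chr1", IRanges(c(1001, 5001, 9001), width = 200))
  gata3 <- GRanges("chr1", IRanges(c(1050, 5050), width = 100))
  nr2f2 <- GRanges("chr1", IRanges(1080, width = 100))
  foxa1 <- GRanges("chr2", IRanges(1001, width = 100))
  tab <- classifyCombinations(anchor,
                              list(GATA3 = gata3, NR2F2 = nr2f2, FOXA1 = foxa1))
  expect_equal(siteCodes(tab), c("110", "100", "000"))
  expect_equal(unname(coverageByCardinality(tab)),
               c(1 / 3, 1 / 3, 1 / 3, 0))
  expect_equal(sum(groupCounts(tab)), 3L)
  expect_error(classifyCombinations(anchor, list(A = gata3, A = nr2f2)),
               "duplicate|named")
})

test_that("a site overlapping two intervals of one factor sets its bit once", {
  anchor <- GRanges("chr1", IRanges(1001, 2000))
  f <- GRanges("chr1", IRanges(c(1001, 1501), width = 100))
  tab <- classifyCombinations(anchor, list(F1 = f))
  expect_equal(siteCodes(tab), "1")
  expect_equal(unname(groupCounts(tab)["1"]), 1L)
})

test_that("combination classes partition the anchor set", {
  set.seed(60)
  anchor <- mergeSelf(rGR(300, maxStart = 100000, maxWidth = 150))
  factors <- list(A = rGR(150, maxStart = 100000),
                  B = rGR(150, maxStart = 100000),
                  C = rGR(150, maxStart = 100000))
  tab <- classifyCombinations(anchor, factors)
  sets <- combinationSiteSets(tab)
  expect_equal(sum(lengths(sets)), length(anchor))
  expect_equal(lengths(sets)[names(sets)],
               setNames(as.integer(groupCounts(tab)[names(sets)]), names(sets)))
  for (i in seq_along(sets)) for (j in seq_along(sets)) if (i < j)
    expect_equal(countOverlapping(sets[[i]], sets[[j]], minBp = 200), 0L)
  # marginal per-factor membership from codes equals independent counting
  for (b in 1:3) {
    fromCodes <- sum(substr(siteCodes(tab), b, b) == "1")
    expect_equal(fromCodes, bruteCountOverlapping(anchor, factors[[b]]))
  }
})

test_that("planted combination probabilities are recovered from generator output", {
  cfg <- simConfig(seed = 9, nSites = 4000)
  sim <- simulateCistromes(cfg)
  tab <- classifyCombinations(sim$anchor, sim$factors)
  cov <- coverageByCardinality(tab)
  planted <- c("0" = 0.15, "1" = 0.24, "2" = 0.36, "3" = 0.25)
  for (d in names(planted))
    expect_lt(abs(cov[[d]] - planted[[d]]), 3 * sqrt(planted[[d]] * (1 - planted[[d]]) / 4000) + 0.005)
  # codes agree with the latent truth table
  expect_gt(mean(siteCodes(tab) == sim$truth$code), 0.999)
})

test_that("pairwiseOverlapMatrix matches a brute-force oracle", {
  a <- mergeSelf(rGR(100, maxStart = 20000))
  expect_true(all(pairwiseOverlapMatrix(list(A = a, B = a)) == 100))
  b <- GenomicRanges::shift(a, 10^6)
  m <- pairwiseOverlapMatrix(list(A = a, B = b))
  expect_equal(unname(m[1, 2]), 0)
  expect_equal(unname(diag(m)), c(100, 100))

  set.seed(61)
  fs <- list(X = rGR(120, maxStart = 15000), Y = rGR(90, maxStart = 15000),
             Z = rGR(150, maxStart = 15000))
  m <- pairwiseOverlapMatrix(fs)
  merged <- lapply(fs, mergeSelf)
  for (i in 1:3) for (j in 1:3) if (i != j)
    expect_equal(m[i, j],
                 100 * bruteCountOverlapping(merged[[i]], merged[[j]]) /
                   length(merged[[i]]))
  expect_error(pairwiseOverlapMatrix(list(A = a)), "2")
  expect_error(pairwiseOverlapMatrix(list(A = a, B = GRanges())), "empty")
})

test_that("nmfBinding validates input and is deterministic given a seed", {
  V <- matrix(abs(rnorm(60)), 20, 3)
  expect_error(nmfBinding(-V, 2), "nonnegative")
  expect_error(nmfBinding(V, 0), "positive")
  expect_error(nmfBinding(V, 5), "rank")
  r1 <- nmfBinding(V, 2, maxIter = 50, seed = 3)
  r2 <- nmfBinding(V, 2, maxIter = 50, seed = 3)
  expect_identical(basisMatrix(r1), basisMatrix(r2))
  expect_identical(coefMatrix(r1), coefMatrix(r2))
})

test_that("NMF error is monotone non-increasing and recovers planted factorizations", {
  set.seed(62)
  V <- matrix(abs(rnorm(90)), 30, 3)
  res <- nmfBinding(V, 2, maxIter = 300)
  expect_true(all(diff(res@errorTrace) <= 1e-9))
  expect_true(all(basisMatrix(res) >= 0))
  expect_true(all(coefMatrix(res) >= 0))

  W0 <- matrix(runif(60, 0.2, 1), 30, 2)
  H0 <- matrix(runif(6, 0.2, 1), 2, 3)
  planted <- nmfBinding(W0 %*% H0, 2, maxIter = 50000, tol = 0, seed = 7)
  expect_lt(reconstructionError(planted), 1e-6)

  # rank = k on a trivially representable dense matrix -> near-zero error
  Wf <- matrix(runif(9, 0.2, 1), 3, 3)
  full <- nmfBinding(Wf %*% diag(c(2, 3, 4)), 3, maxIter = 50000, tol = 0,
                     seed = 1, nStart = 3)
  expect_lt(reconstructionError(full), 1e-6)
})

test_that("per-class anchor signal is highest at triple-bound sites", {
  cfg <- simConfig(seed = 10, nSites = 3000)
  sim <- simulateCistromes(cfg)
  tab <- classifyCombinations(sim$anchor, sim$factors)
  trk <- simulateTags(cfg, sim$anchor, anchorMultipliers(cfg, siteCodes(tab)),
                      seed = 111)
  bm <- binnedDensity(sim$anchor, trk)
  central <- rowMeans(binValues(bm)[, 20:21])
  byClass <- tapply(central, siteCodes(tab), mean)
  expect_equal(names(which.max(byClass)), "111")
})
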