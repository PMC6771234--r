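# End-to-end demo pipeline on synthetic cistromes: simulate -> cofactor
# screen -> co-binding codes -> binned densities -> super-enhancers ->
# knockdown perturbation -> expression-code survival. Writes stage TSV/BED
# outputs, a deterministic summary (byte-identical across reruns with the
# same config) and a run manifest (the only file carrying a timestamp).

.centralMean <- function(bm) {
  nb <- nBins(bm)
  mid <- c(nb %/% 2L, nb %/% 2L + 1L)
  rowMeans(binValues(bm)[, mid, drop = FALSE])
}

.fmt <- function(x) sprintf("%.6g", x)

#' Run the end-to-end synthetic-cistrome demo pipeline
#'
#' Chains every analysis stage of the package on generator output:
#' cofactor overlap screen, combinatorial co-binding classification,
#' cardinality-stratified anchor signal, condition-free intensity
#' correlation, super-enhancer stitch-and-rank at triple-bound sites,
#' knockdown binding-change classification with ATAC-style peak loss, and
#' E-code Kaplan-Meier/log-rank survival stratification. All stage outputs
#' plus `summary.txt` (deterministic given the config) and `manifest.json`
#' are written to `outDir`.
#'
#' @param config a [simConfig] object.
#' @param outDir output directory (created if needed).
#' @param writeFiles write per-stage BED/TSV outputs (default TRUE;
#'   `summary.txt` and the manifest are always written).
#' @return invisibly, a list with all stage results and the summary lines.
#' @export
runPipeline <- function(config = simConfig(), outDir = tempfile("cistrio_"),
                        writeFiles = TRUE) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sm <- character(0)
  say <- function(...) message("[cistrio] ", ...)

  say("stage 1/7: simulating cistromes (n = ", config$nSites, " latent sites)")
  sim <- simulateCistromes(config)
  k <- length(config$factors)
  sm <- c(sm, sprintf("n_anchor_sites\t%d", length(sim$anchor)))
  if (writeFiles) {
    writePeakBed(sim$anchor, file.path(outDir, "anchor.bed"))
    for (f in names(sim$factors))
      writePeakBed(sim$factors[[f]], file.path(outDir, paste0(f, ".bed")))
  }

  say("stage 2/7: cofactor overlap screen")
  screen <- overlapScreen(sim$anchor, sim$factors)
  for (i in seq_len(nrow(screen)))
    sm <- c(sm, sprintf("overlap_coefficient_anchor\t%s\t%s",
                        screen$factor_label[i], .fmt(screen$coefficient_anchor[i])))
  if (writeFiles)
    utils::write.table(screen, file.path(outDir, "screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  say("stage 3/7: combinatorial co-binding classification")
  combos <- classifyCombinations(sim$anchor, sim$factors)
  cov <- coverageByCardinality(combos)
  for (d in names(cov))
    sm <- c(sm, sprintf("coverage_cardinality_%s\t%s", d, .fmt(cov[[d]])))
  sm <- c(sm, sprintf("coverage_any_factor\t%s", .fmt(1 - cov[["0"]])))
  if (writeFiles) {
    gc <- groupCounts(combos)
    utils::write.table(data.frame(code = names(gc), n = as.integer(gc)),
                       file.path(outDir, "combination_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pw <- pairwiseOverlapMatrix(sim$factors)
    utils::write.table(round(pw, 3), file.path(outDir, "pairwise_overlap_pct.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }

  say("stage 4/7: binned anchor signal by co-binding cardinality")
  mult <- anchorMultipliers(config, siteCodes(combos))
  anchorTrack <- simulateTags(config, sim$anchor, mult, label = "anchor_ctrl",
                              seed = config$seed + 11L)
  dens <- binnedDensity(sim$anchor, anchorTrack)
  central <- .centralMean(dens)
  card <- .popcount(siteCodes(combos))
  for (d in sort(unique(card)))
    sm <- c(sm, sprintf("central_signal_cardinality_%d\t%s", d,
                        .fmt(mean(central[card == d]))))
  replTrack <- simulateTags(config, sim$anchor, mult, label = "anchor_repl",
                            seed = config$seed + 12L)
  corr <- intensityCorrelation(siteSignal(sim$anchor, anchorTrack),
                               siteSignal(sim$anchor, replTrack))
  sm <- c(sm, sprintf("prepost_r_squared\t%s", .fmt(corr$r_squared)))
  if (writeFiles) {
    prof <- meanProfile(dens)
    utils::write.table(data.frame(bin_offset = (seq_along(prof) - 1L) * 100L - 2000L,
                                  mean_density = prof),
                       file.path(outDir, "anchor_profile.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  say("stage 5/7: super-enhancer stitch-and-rank at triple-bound sites")
  cobound <- sim$anchor[card == k]
  stitched <- stitchRegions(cobound)
  seSig <- simulateSeSignals(config, length(stitched), seed = config$seed + 21L)
  mcols(stitched)$signal <- seSig$signal
  se <- rankAndCut(stitched)
  sm <- c(sm, sprintf("n_stitched_regions\t%d", length(stitched)))
  sm <- c(sm, sprintf("n_super_enhancers\t%d", nSuper(se)))
  sm <- c(sm, sprintf("super_enhancer_fraction\t%s",
                      .fmt(nSuper(se) / length(stitched))))
  set.seed(config$seed + 22L)
  nGenes <- 3000L
  geneChrom <- sample(names(config$genome), nGenes, replace = TRUE,
                      prob = config$genome / sum(config$genome))
  tss <- data.frame(gene = sprintf("gene_%04d", seq_len(nGenes)),
                    chrom = geneChrom,
                    pos = floor(runif(nGenes, 0, config$genome[geneChrom])),
                    strand = "+", stringsAsFactors = FALSE)
  ga <- assignNearestGene(superRegions(se), tss)
  sm <- c(sm, sprintf("super_enhancer_genes_unique\t%d", ga$uniqueGenes))
  if (writeFiles) {
    utils::write.table(ga$assignments,
                       file.path(outDir, "super_enhancer_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (writeFiles) {
    reg <- se@regions
    df <- data.frame(chrom = as.character(seqnames(reg)),
                     start = start(reg) - 1, end = end(reg),
                     signal = mcols(reg)$signal,
                     is_super = as.integer(mcols(reg)$isSuper))
    utils::write.table(df, file.path(outDir, "stitched_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  say("stage 6/7: knockdown perturbation")
  cfgP <- config
  cfgP$comboProbs <- .perturbComboProbs()
  cfgP$seed <- config$seed + 31L
  simP <- simulateCistromes(cfgP)
  nr2f2bit <- which(cfgP$factors == cfgP$knockdownTarget)
  targeted <- substr(simP$truth$code, nr2f2bit, nr2f2bit) == "1"
  ctrl <- simulateTags(cfgP, simP$anchor, rep(1, length(simP$anchor)),
                       label = "shCtrl", seed = cfgP$seed + 1L,
                       totalMapped = 1e7)
  kdMult <- ifelse(targeted, cfgP$knockdownAttenuation, 1)
  kd <- simulateTags(cfgP, simP$anchor, kdMult, label = "shKD",
                     seed = cfgP$seed + 2L, totalMapped = 1e7)
  change <- classifyBindingChange(simP$anchor, ctrl, kd)
  fr <- classFractions(change)
  for (cl in names(fr))
    sm <- c(sm, sprintf("binding_change_%s\t%s", cl, .fmt(fr[[cl]])))
  set.seed(cfgP$seed + 3L)
  keep <- runif(length(simP$anchor)) >= config$atacLossRate
  atacDiff <- peaksetDiff(simP$anchor, simP$anchor[keep])
  sm <- c(sm, sprintf("atac_lost_fraction\t%s", .fmt(atacDiff@lostFraction)))
  if (writeFiles) {
    df <- data.frame(chrom = as.character(seqnames(simP$anchor)),
                     start = start(simP$anchor) - 1, end = end(simP$anchor),
                     log2fc = round(change@log2fc, 4),
                     class = siteClasses(change))
    utils::write.table(df, file.path(outDir, "binding_change.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  say("stage 7/7: expression-code survival stratification")
  coh <- simulateCohort(config, seed = config$seed + 41L)
  cohort <- encodeExpression(coh$cohort, config$factors)
  grp <- ecodeGroups(cohort, minGroup = 5)
  kept <- cohort@ecode %in% grp$kept
  lr <- logrankTest(cohort@time[kept], cohort@event[kept],
                    cohort@ecode[kept])
  sm <- c(sm, sprintf("ecode_groups_kept\t%d", length(grp$kept)))
  sm <- c(sm, sprintf("logrank_statistic\t%s", .fmt(lr$statistic)))
  sm <- c(sm, sprintf("logrank_p\t%s", .fmt(lr$p_value)))
  if (writeFiles) {
    curves <- kmByCode(cohort, minGroup = 5)
    km <- do.call(rbind, lapply(curves, function(cv)
      data.frame(group = cv@label, time = cv@times, survival = cv@survival)))
    utils::write.table(km, file.path(outDir, "km_curves.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  writeLines(sm, file.path(outDir, "summary.txt"))
  manifest <- list(tool = "cistrio", version = as.character(packageVersion("cistrio")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "genome")],
                   genome = as.list(config$genome),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", outDir)
  invisible(list(sim = sim, screen = screen, combos = combos,
                 density = dens, correlation = corr, superEnhancers = se,
                 seTruth = seSig, geneAssignments = ga,
                 bindingChange = change, atacDiff = atacDiff,
                 cohort = cohort, logrank = lr, summary = sm,
                 outDir = outDir))
}
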