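# Knockdown perturbation analysis: classify anchor sites into
# weaker/unchanged/stronger by log2 fold change of normalized signal
# between a control and a knockdown track, and quantify peak loss/gain
# between two peak sets.

#' Classify binding change between control and knockdown
#'
#' Per-site signals come from [siteSignal] (each site's own span, library
#' normalized); `log2fc = log2((kd + pc) / (ctrl + pc))`. A site is
#' "weaker" if `log2fc <= -log2(fcThreshold)`, "stronger" if
#' `log2fc >= +log2(fcThreshold)`, otherwise "unchanged". Swapping the two
#' tracks exactly swaps the weaker and stronger classes.
#'
#' @param sites anchor `GRanges`.
#' @param control,knockdown [TagTrack-class] objects for the two conditions.
#' @param fcThreshold fold-change threshold (> 1), default 1.5.
#' @param pseudocount added to both signals before the ratio.
#' @return a [BindingChangeTable-class].
#' @export
classifyBindingChange <- function(sites, control, knockdown,
                                  fcThreshold = 1.5, pseudocount = 0.5) {
  if (fcThreshold <= 1) stop("fcThreshold must be > 1")
  sc <- siteSignal(sites, control)
  sk <- siteSignal(sites, knockdown)
  lfc <- log2((sk + pseudocount) / (sc + pseudocount))
  thr <- log2(fcThreshold)
  cls <- ifelse(lfc <= -thr, "weaker", ifelse(lfc >= thr, "stronger", "unchanged"))
  fr <- vapply(c("weaker", "unchanged", "stronger"),
               function(cl) mean(cls == cl), numeric(1))
  new("BindingChangeTable", sites = sites, signalControl = sc,
      signalKnockdown = sk, log2fc = lfc, siteClass = as.character(cls),
      classFractions = fr,
      params = list(fcThreshold = fcThreshold, pseudocount = pseudocount))
}

#' Peak gain/loss between two conditions
#'
#' Both peak sets are self-merged; a condition-A peak is "lost" if it shares
#' no `minBp` overlap with any condition-B peak. `lostFraction` is the
#' fraction of A peaks lost.
#'
#' @param a,b `GRanges` peak sets (e.g. ATAC peaks in shCtrl and shNR2F2).
#' @param minBp minimum shared bases to call an overlap.
#' @return a [PeakSetDiff-class].
#' @export
peaksetDiff <- function(a, b, minBp = 1) {
  aM <- mergeSelf(a)
  bM <- mergeSelf(b)
  shared <- countOverlapping(aM, bM, minBp)
  onlyA <- length(aM) - shared
  onlyB <- length(bM) - countOverlapping(bM, aM, minBp)
  new("PeakSetDiff", nOnlyA = as.integer(onlyA), nOnlyB = as.integer(onlyB),
      nShared = as.integer(shared),
      lostFraction = if (length(aM)) onlyA / length(aM) else 0)
}

#' Per-class mean signal profiles across one or more tracks
#'
#' For each binding-change class with at least one site, computes the mean
#' binned-density profile of every supplied track. The returned heatmap row
#' order within each class is descending control anchor signal.
#'
#' @param table a [BindingChangeTable-class].
#' @param tracks named list of [TagTrack-class] objects.
#' @param flank,binWidth window parameters passed to [binnedDensity].
#' @return list per class, each with `profiles` (named list of bin-mean
#'   vectors per track), `n` (sites in the class) and `order` (indices of
#'   the class's sites sorted by descending control signal).
#' @export
stratifiedProfiles <- function(table, tracks, flank = 2000, binWidth = 100) {
  stopifnot(is(table, "BindingChangeTable"))
  if (is.null(names(tracks))) stop("tracks must be a named list")
  out <- list()
  for (cl in c("weaker", "unchanged", "stronger")) {
    idx <- which(table@siteClass == cl)
    if (!length(idx)) {
      warning("class '", cl, "' is empty; omitted")
      next
    }
    sites <- table@sites[idx]
    profs <- lapply(tracks, function(tr)
      meanProfile(binnedDensity(sites, tr, flank = flank, binWidth = binWidth)))
    out[[cl]] <- list(profiles = profs, n = length(idx),
                      order = idx[order(-table@signalControl[idx])])
  }
  out
}
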