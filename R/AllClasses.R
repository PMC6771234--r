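#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqnames sortSeqlevels
#' @importFrom stats rnorm runif rpois rexp rgamma rbinom pchisq setNames
#' @importFrom utils packageVersion
NULL

#' TagTrack: mapped-tag positions with a library size
#'
#' A `TagTrack` holds one genomic position per mapped read (the "tag") plus
#' the total number of mapped reads in the library. It is the source of all
#' binned densities and per-site signals, which are normalized to reads per
#' 10 million mapped reads per 100-bp bin.
#'
#' Tags are stored as width-1 [GenomicRanges::GRanges] (1-based); the total
#' mapped count may exceed the number of stored tags (e.g. tags restricted
#' to chromosomes of interest).
#'
#' @slot label character scalar naming the track (factor/condition).
#' @slot tags width-1 `GRanges` of tag positions, sorted.
#' @slot totalMapped numeric scalar, total mapped reads (> 0).
#' @export
setClass("TagTrack",
  slots = c(label = "character", tags = "GRanges", totalMapped = "numeric"))

setValidity("TagTrack", function(object) {
  msg <- character()
  if (length(object@label) != 1L) msg <- c(msg, "label must be a single string")
  if (length(object@tags) && any(width(object@tags) != 1L))
    msg <- c(msg, "tags must all have width 1")
  if (length(object@totalMapped) != 1L || is.na(object@totalMapped) ||
      object@totalMapped <= 0)
    msg <- c(msg, "totalMapped must be a positive scalar")
  else if (object@totalMapped < length(object@tags))
    msg <- c(msg, "totalMapped must be >= number of stored tags")
  if (length(msg)) msg else TRUE
})

#' BinnedMatrix: site-by-bin normalized read densities
#'
#' Rows are sites, columns are fixed-width bins tiling a window centered on
#' each site. Values are in units of reads per 10 million mapped reads per
#' bin (the "10*rpm/bp" unit with 100-bp bins).
#'
#' @slot values nonnegative numeric matrix, sites x bins.
#' @slot binWidth bin width in bp.
#' @slot flank half-window in bp; `ncol(values) * binWidth == 2 * flank`.
#' @slot siteIds row labels.
#' @export
setClass("BinnedMatrix",
  slots = c(values = "matrix", binWidth = "numeric", flank = "numeric",
            siteIds = "character"))

setValidity("BinnedMatrix", function(object) {
  msg <- character()
  if (any(object@values < 0)) msg <- c(msg, "values must be nonnegative")
  if (ncol(object@values) * object@binWidth != 2 * object@flank)
    msg <- c(msg, "n_bins * bin_width must equal the window width (2*flank)")
  if (length(object@siteIds) != nrow(object@values))
    msg <- c(msg, "siteIds must align with rows")
  if (length(msg)) msg else TRUE
})

#' CombinationTable: per-site co-binding codes over k factor cistromes
#'
#' Each anchor site receives a binary code of length k ("S-code"); bit i is 1
#' iff the site overlaps the i-th factor's peak set. With the factor order
#' (GATA3, NR2F2, FOXA1), code "110" marks sites bound by GATA3 and NR2F2
#' but not FOXA1; "000" sites are uncovered.
#'
#' @slot anchor the anchor `GRanges` (one code per range, same order).
#' @slot factorOrder ordered factor labels defining bit positions.
#' @slot codes character vector of binary codes, one per anchor site.
#' @slot groupCounts named integer, sites per code (all 2^k codes).
#' @slot coverageByCardinality named numeric, fraction of anchor sites bound
#'   by exactly 0, 1, ..., k factors (sums to 1).
#' @export
setClass("CombinationTable",
  slots = c(anchor = "GRanges", factorOrder = "character",
            codes = "character", groupCounts = "integer",
            coverageByCardinality = "numeric"))

setValidity("CombinationTable", function(object) {
  msg <- character()
  if (length(object@codes) != length(object@anchor))
    msg <- c(msg, "one code per anchor site required")
  if (sum(object@groupCounts) != length(object@anchor))
    msg <- c(msg, "group counts must sum to the number of anchor sites")
  if (length(object@anchor) &&
      abs(sum(object@coverageByCardinality) - 1) > 1e-9)
    msg <- c(msg, "cardinality coverage fractions must sum to 1")
  if (length(object@codes) && !all(grepl("^[01]+$", object@codes)))
    msg <- c(msg, "codes must be binary strings")
  if (length(msg)) msg else TRUE
})

#' NMFResult: nonnegative matrix factorization of a binding-signal matrix
#'
#' @slot basis nonnegative W (sites x rank).
#' @slot coefficients nonnegative H (rank x factors).
#' @slot rank factorization rank.
#' @slot errorTrace Frobenius reconstruction error per iteration
#'   (non-increasing under multiplicative updates).
#' @export
setClass("NMFResult",
  slots = c(basis = "matrix", coefficients = "matrix", rank = "integer",
            errorTrace = "numeric"))

setValidity("NMFResult", function(object) {
  msg <- character()
  if (any(object@basis < 0) || any(object@coefficients < 0))
    msg <- c(msg, "W and H must be nonnegative")
  if (ncol(object@basis) != object@rank || nrow(object@coefficients) != object@rank)
    msg <- c(msg, "factor dimensions must match rank")
  if (length(msg)) msg else TRUE
})

#' StitchRankResult: stitched enhancers ranked by signal with a tangent cutoff
#'
#' Regions are stitched enhancer constituents; each carries a summed
#' normalized signal. Regions whose signal exceeds the slope-1 tangent cutoff
#' of the scaled rank-signal curve are flagged as super-enhancers.
#'
#' @slot regions `GRanges` sorted ascending by signal, with metadata columns
#'   `signal`, `constituentCount`, `isSuper`.
#' @slot cutoffSignal cutoff on the original signal scale.
#' @slot nSuper number of flagged regions.
#' @export
setClass("StitchRankResult",
  slots = c(regions = "GRanges", cutoffSignal = "numeric", nSuper = "integer"))

setValidity("StitchRankResult", function(object) {
  msg <- character()
  mc <- mcols(object@regions)
  if (!all(c("signal", "isSuper") %in% colnames(mc)))
    msg <- c(msg, "regions need 'signal' and 'isSuper' metadata columns")
  else {
    if (is.unsorted(mc$signal)) msg <- c(msg, "regions must be sorted ascending by signal")
    if (!identical(as.logical(mc$isSuper), mc$signal > object@cutoffSignal))
      msg <- c(msg, "isSuper flags must equal signal > cutoffSignal")
    if (object@nSuper != sum(mc$isSuper)) msg <- c(msg, "nSuper must count the flags")
  }
  if (length(msg)) msg else TRUE
})

#' BindingChangeTable: weaker/unchanged/stronger classification of sites
#'
#' Per-site normalized signal in a control and a knockdown condition, the
#' log2 fold change (with pseudocount), and the resulting three-way class.
#'
#' @slot sites anchor `GRanges`.
#' @slot signalControl,signalKnockdown per-site normalized signals.
#' @slot log2fc per-site log2((kd + pc) / (ctrl + pc)).
#' @slot siteClass character, one of "weaker", "unchanged", "stronger".
#' @slot classFractions named numeric over the three classes (sums to 1).
#' @slot params list with `fcThreshold` and `pseudocount` used.
#' @export
setClass("BindingChangeTable",
  slots = c(sites = "GRanges", signalControl = "numeric",
            signalKnockdown = "numeric", log2fc = "numeric",
            siteClass = "character", classFractions = "numeric", params = "list"))

setValidity("BindingChangeTable", function(object) {
  msg <- character()
  n <- length(object@sites)
  if (length(object@siteClass) != n || length(object@log2fc) != n)
    msg <- c(msg, "per-site vectors must align with sites")
  if (!all(object@siteClass %in% c("weaker", "unchanged", "stronger")))
    msg <- c(msg, "unknown class label")
  if (n && abs(sum(object@classFractions) - 1) > 1e-9)
    msg <- c(msg, "class fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' PeakSetDiff: peak gain/loss between two conditions
#'
#' Counts are computed on self-merged peak sets; `lostFraction` is the
#' fraction of condition-A peaks with no overlap in condition B.
#'
#' @slot nOnlyA,nOnlyB,nShared integer counts (shared counted in A's units).
#' @slot lostFraction nOnlyA / |A|.
#' @export
setClass("PeakSetDiff",
  slots = c(nOnlyA = "integer", nOnlyB = "integer", nShared = "integer",
            lostFraction = "numeric"))

setValidity("PeakSetDiff", function(object) {
  nA <- object@nOnlyA + object@nShared
  if (nA > 0 && abs(object@lostFraction - object@nOnlyA / nA) > 1e-9)
    "lostFraction inconsistent with counts" else TRUE
})

#' CohortTable: patient expression, follow-up and binary expression codes
#'
#' @slot patientIds character ids.
#' @slot expression nonnegative patients x genes matrix (no missing values).
#' @slot time follow-up times (> 0, consistent units).
#' @slot event logical, TRUE if the event (metastasis/death) was observed.
#' @slot ecode per-patient binary code over `geneOrder` (may be empty before
#'   [encodeExpression] is applied).
#' @slot geneOrder ordered genes defining the code bits.
#' @export
setClass("CohortTable",
  slots = c(patientIds = "character", expression = "matrix", time = "numeric",
            event = "logical", ecode = "character", geneOrder = "character"))

setValidity("CohortTable", function(object) {
  msg <- character()
  n <- length(object@patientIds)
  if (nrow(object@expression) != n) msg <- c(msg, "expression rows must match patients")
  if (any(is.na(object@expression))) msg <- c(msg, "expression must have no missing values")
  if (any(object@expression < 0)) msg <- c(msg, "expression must be nonnegative")
  if (length(object@time) != n || any(object@time <= 0))
    msg <- c(msg, "time must be positive, one per patient")
  if (length(object@event) != n) msg <- c(msg, "event must align with patients")
  if (length(object@ecode) && length(object@ecode) != n)
    msg <- c(msg, "ecode must be empty or one per patient")
  if (length(object@ecode) && length(object@geneOrder) &&
      any(nchar(object@ecode) != length(object@geneOrder)))
    msg <- c(msg, "ecode length must equal the number of coded genes")
  if (length(msg)) msg else TRUE
})

#' SurvivalCurve: Kaplan-Meier product-limit estimate for one group
#'
#' @slot times sorted time points (starting at 0).
#' @slot survival step-function values, starting at 1, non-increasing.
#' @slot atRisk number at risk just before each time.
#' @slot label group label.
#' @export
setClass("SurvivalCurve",
  slots = c(times = "numeric", survival = "numeric", atRisk = "numeric",
            label = "character"))

setValidity("SurvivalCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@survival))
    msg <- c(msg, "times and survival must align")
  if (length(object@survival)) {
    if (object@survival[1] != 1) msg <- c(msg, "curve must start at 1")
    if (is.unsorted(rev(object@survival))) msg <- c(msg, "survival must be non-increasing")
    if (any(object@survival < 0) || any(object@survival > 1))
      msg <- c(msg, "survival must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})
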