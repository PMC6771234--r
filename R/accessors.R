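#' @rdname TagTrack-class
#' @export
setMethod("totalMapped", "TagTrack", function(x) x@totalMapped)

#' @rdname TagTrack-class
#' @export
setMethod("tagCount", "TagTrack", function(x) length(x@tags))

#' @rdname TagTrack-class
#' @export
setMethod("trackLabel", "TagTrack", function(x) x@label)

#' @rdname TagTrack-class
#' @export
setMethod("show", "TagTrack", function(object) {
  cat("TagTrack '", object@label, "': ", length(object@tags),
      " tags on ", length(seqlevels(object@tags)), " chromosome(s), ",
      format(object@totalMapped, big.mark = ","), " total mapped reads\n",
      sep = "")
})

#' @rdname BinnedMatrix-class
#' @export
setMethod("binValues", "BinnedMatrix", function(x) x@values)

#' @rdname BinnedMatrix-class
#' @export
setMethod("nBins", "BinnedMatrix", function(x) ncol(x@values))

#' @rdname BinnedMatrix-class
#' @export
setMethod("show", "BinnedMatrix", function(object) {
  cat("BinnedMatrix: ", nrow(object@values), " sites x ", ncol(object@values),
      " bins of ", object@binWidth, " bp (window +/-", object@flank,
      " bp), units reads/10M mapped/bin\n", sep = "")
})

#' @describeIn meanProfile column means of the density matrix; errors on an
#'   empty matrix.
#' @export
setMethod("meanProfile", "BinnedMatrix", function(x) {
  if (nrow(x@values) == 0L) stop("cannot average an empty BinnedMatrix")
  colMeans(x@values)
})

#' @rdname CombinationTable-class
#' @export
setMethod("siteCodes", "CombinationTable", function(x) x@codes)

#' @rdname CombinationTable-class
#' @export
setMethod("groupCounts", "CombinationTable", function(x) x@groupCounts)

#' @rdname CombinationTable-class
#' @export
setMethod("coverageByCardinality", "CombinationTable",
          function(x) x@coverageByCardinality)

#' @rdname CombinationTable-class
#' @export
setMethod("factorOrder", "CombinationTable", function(x) x@factorOrder)

#' @rdname CombinationTable-class
#' @export
setMethod("show", "CombinationTable", function(object) {
  k <- length(object@factorOrder)
  cat("CombinationTable: ", length(object@anchor), " anchor sites x ", k,
      " factors (", paste(object@factorOrder, collapse = ", "), ")\n",
      sep = "")
  cov <- object@coverageByCardinality
  cat("  coverage by cardinality:",
      paste(sprintf("%s:%.3f", names(cov), cov), collapse = " "), "\n")
})

#' @rdname NMFResult-class
#' @export
setMethod("basisMatrix", "NMFResult", function(x) x@basis)

#' @rdname NMFResult-class
#' @export
setMethod("coefMatrix", "NMFResult", function(x) x@coefficients)

#' @rdname NMFResult-class
#' @export
setMethod("reconstructionError", "NMFResult", function(x) tail(x@errorTrace, 1L))

#' @rdname NMFResult-class
#' @export
setMethod("show", "NMFResult", function(object) {
  cat("NMFResult: rank ", object@rank, ", ", length(object@errorTrace),
      " iterations, final Frobenius error ",
      format(tail(object@errorTrace, 1L), digits = 4), "\n", sep = "")
})

#' @rdname StitchRankResult-class
#' @export
setMethod("superRegions", "StitchRankResult",
          function(x) x@regions[mcols(x@regions)$isSuper])

#' @rdname StitchRankResult-class
#' @export
setMethod("cutoffSignal", "StitchRankResult", function(x) x@cutoffSignal)

#' @rdname StitchRankResult-class
#' @export
setMethod("nSuper", "StitchRankResult", function(x) x@nSuper)

#' @rdname StitchRankResult-class
#' @export
setMethod("show", "StitchRankResult", function(object) {
  cat("StitchRankResult: ", length(object@regions), " stitched regions, ",
      object@nSuper, " super-enhancers above signal cutoff ",
      format(object@cutoffSignal, digits = 4), "\n", sep = "")
})

#' @rdname BindingChangeTable-class
#' @export
setMethod("classFractions", "BindingChangeTable", function(x) x@classFractions)

#' @rdname BindingChangeTable-class
#' @export
setMethod("siteClasses", "BindingChangeTable", function(x) x@siteClass)

#' @rdname BindingChangeTable-class
#' @export
setMethod("show", "BindingChangeTable", function(object) {
  fr <- object@classFractions
  cat("BindingChangeTable: ", length(object@sites), " sites; ",
      paste(sprintf("%s %.1f%%", names(fr), 100 * fr), collapse = ", "),
      " (|log2FC| threshold ", format(log2(object@params$fcThreshold), digits = 3),
      ")\n", sep = "")
})

#' @rdname PeakSetDiff-class
#' @export
setMethod("show", "PeakSetDiff", function(object) {
  cat("PeakSetDiff: only-A ", object@nOnlyA, ", shared ", object@nShared,
      ", only-B ", object@nOnlyB, "; lost fraction ",
      sprintf("%.3f", object@lostFraction), "\n", sep = "")
})

#' @rdname CohortTable-class
#' @export
setMethod("ecodes", "CohortTable", function(x) x@ecode)

#' @rdname CohortTable-class
#' @export
setMethod("expressionMatrix", "CohortTable", function(x) x@expression)

#' @rdname CohortTable-class
#' @export
setMethod("show", "CohortTable", function(object) {
  cat("CohortTable: ", length(object@patientIds), " patients, ",
      ncol(object@expression), " genes, ", sum(object@event), " events\n",
      sep = "")
  if (length(object@ecode))
    cat("  E-codes over (", paste(object@geneOrder, collapse = ", "), "): ",
        length(unique(object@ecode)), " distinct codes\n", sep = "")
})

#' @rdname SurvivalCurve-class
#' @export
setMethod("show", "SurvivalCurve", function(object) {
  cat("SurvivalCurve '", object@label, "': ", length(object@times),
      " time points, final S(t) = ",
      sprintf("%.3f", tail(object@survival, 1L)), "\n", sep = "")
})
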