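#' @rdname TagTrack-class
#' @param object,x an object.
#' @export
setGeneric("totalMapped", function(x) standardGeneric("totalMapped"))

#' @rdname TagTrack-class
#' @export
setGeneric("tagCount", function(x) standardGeneric("tagCount"))

#' @rdname TagTrack-class
#' @export
setGeneric("trackLabel", function(x) standardGeneric("trackLabel"))

#' @rdname BinnedMatrix-class
#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))

#' @rdname BinnedMatrix-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Column-wise mean signal profile of a binned matrix
#'
#' @param x a [BinnedMatrix-class].
#' @return numeric vector of length `nBins(x)`: the mean density per bin.
#' @export
setGeneric("meanProfile", function(x) standardGeneric("meanProfile"))

#' @rdname CombinationTable-class
#' @export
setGeneric("siteCodes", function(x) standardGeneric("siteCodes"))

#' @rdname CombinationTable-class
#' @export
setGeneric("groupCounts", function(x) standardGeneric("groupCounts"))

#' @rdname CombinationTable-class
#' @export
setGeneric("coverageByCardinality", function(x) standardGeneric("coverageByCardinality"))

#' @rdname CombinationTable-class
#' @export
setGeneric("factorOrder", function(x) standardGeneric("factorOrder"))

#' @rdname NMFResult-class
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname NMFResult-class
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))

#' @rdname NMFResult-class
#' @export
setGeneric("reconstructionError", function(x) standardGeneric("reconstructionError"))

#' @rdname StitchRankResult-class
#' @export
setGeneric("superRegions", function(x) standardGeneric("superRegions"))

#' @rdname StitchRankResult-class
#' @export
setGeneric("cutoffSignal", function(x) standardGeneric("cutoffSignal"))

#' @rdname StitchRankResult-class
#' @export
setGeneric("nSuper", function(x) standardGeneric("nSuper"))

#' @rdname BindingChangeTable-class
#' @export
setGeneric("classFractions", function(x) standardGeneric("classFractions"))

#' @rdname BindingChangeTable-class
#' @export
setGeneric("siteClasses", function(x) standardGeneric("siteClasses"))

#' @rdname CohortTable-class
#' @export
setGeneric("ecodes", function(x) standardGeneric("ecodes"))

#' @rdname CohortTable-class
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))
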