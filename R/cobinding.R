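# Combinatorial co-binding classification: each anchor site gets a binary
# S-code over an ordered factor list (bit i = 1 iff the site overlaps factor
# i), e.g. "110" over (GATA3, NR2F2, FOXA1) = bound by GATA3 and NR2F2.

.allCodes <- function(k) {
  if (k == 0L) return(character(0))
  apply(as.matrix(expand.grid(rep(list(c("0", "1")), k))[k:1]), 1L,
        paste0, collapse = "")
}

.popcount <- function(codes) {
  vapply(strsplit(codes, ""), function(b) sum(b == "1"), integer(1))
}

#' Classify anchor sites by combinatorial factor co-binding
#'
#' Assigns each anchor site a binary code of length k over the given factor
#' order; bit i is 1 iff the site shares at least `minBp` bases with factor
#' i's peak set (Boolean membership: multiple overlapping intervals of one
#' factor still set the bit once). The codes partition the anchor set;
#' coverage by cardinality gives the fraction of sites bound by exactly
#' 0..k factors, with "00...0" sites counted as uncovered.
#'
#' @param anchor `GRanges` of anchor sites.
#' @param factors named list of `GRanges`, in the bit order wanted (e.g.
#'   GATA3, NR2F2, FOXA1).
#' @param minBp minimum shared bases to call an overlap.
#' @return a [CombinationTable-class].
#' @export
classifyCombinations <- function(anchor, factors, minBp = 1) {
  k <- length(factors)
  if (k < 1L || k > 8L) stop("between 1 and 8 factor sets are supported")
  labs <- names(factors)
  if (is.null(labs) || any(!nzchar(labs))) stop("factors must be a named list")
  if (anyDuplicated(labs)) stop("duplicate factor labels: ",
                                paste(labs[duplicated(labs)], collapse = ", "))
  bits <- vapply(factors, function(f) {
    af <- .alignSeqlevels(anchor, f)
    as.integer(countOverlaps(af[[1]], af[[2]], minoverlap = minBp,
                             ignore.strand = TRUE) > 0L)
  }, integer(length(anchor)))
  bits <- matrix(bits, ncol = k)
  codes <- apply(bits, 1L, paste0, collapse = "")
  if (!length(anchor)) codes <- character(0)
  all_codes <- .allCodes(k)
  counts <- setNames(integer(length(all_codes)), all_codes)
  tab <- table(codes)
  counts[names(tab)] <- as.integer(tab)
  card <- .popcount(all_codes)
  cov <- vapply(0:k, function(d) sum(counts[card == d]), numeric(1))
  cov <- if (length(anchor)) cov / length(anchor) else rep(0, k + 1)
  names(cov) <- as.character(0:k)
  new("CombinationTable", anchor = anchor, factorOrder = labs, codes = codes,
      groupCounts = counts, coverageByCardinality = cov)
}

#' Split the anchor set into per-code site sets
#'
#' @param table a [CombinationTable-class].
#' @param dropEmpty drop codes with no sites (default TRUE).
#' @return named list of `GRanges`, pairwise disjoint, union = anchor set.
#' @export
combinationSiteSets <- function(table, dropEmpty = TRUE) {
  stopifnot(is(table, "CombinationTable"))
  codes <- names(table@groupCounts)
  if (dropEmpty) codes <- codes[table@groupCounts[codes] > 0L]
  setNames(lapply(codes, function(cd) table@anchor[table@codes == cd]), codes)
}

#' Pairwise percent-overlap matrix between factor cistromes
#'
#' Entry (i, j) is 100 x (merged peaks of factor i overlapping factor j) /
#' (merged peak count of factor i); the diagonal is 100.
#'
#' @param factors named list of >= 2 nonempty `GRanges`.
#' @param minBp minimum shared bases to call an overlap.
#' @return k x k numeric matrix of percentages, dimnames = factor labels.
#' @export
pairwiseOverlapMatrix <- function(factors, minBp = 1) {
  k <- length(factors)
  if (k < 2L) stop("need at least 2 factor sets")
  if (any(lengths(factors) == 0L)) stop("empty factor peak set")
  merged <- lapply(factors, mergeSelf)
  m <- matrix(100, k, k, dimnames = list(names(factors), names(factors)))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    m[i, j] <- 100 * countOverlapping(merged[[i]], merged[[j]], minBp) /
      length(merged[[i]])
  m
}
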