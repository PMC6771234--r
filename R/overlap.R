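# Overlap arithmetic on peak GRanges and the cofactor overlap screen.
# Chromosome matching is literal string equality (distinct seqlevels never
# overlap); strand is always ignored.

# Sort with lexicographically ordered seqlevels so output order is stable
# regardless of the order chromosomes appear in the input.
.sortGR <- function(gr) {
  sort(GenomeInfoDb::sortSeqlevels(gr))
}

.alignSeqlevels <- function(a, b) {
  sl <- union(seqlevels(a), seqlevels(b))
  seqlevels(a) <- sl
  seqlevels(b) <- sl
  list(a, b)
}

#' Self-merge a peak set
#'
#' Merges intervals on the same chromosome that overlap or lie within `gap`
#' bp of each other, yielding a sorted, non-overlapping peak set. With
#' `gap = 0` the union of covered bases is preserved exactly.
#'
#' @param peaks a `GRanges`.
#' @param gap maximum separation (bp, >= 0) at which intervals are merged.
#' @return sorted, merged `GRanges`.
#' @examples
#' gr <- GenomicRanges::GRanges(c("chr1", "chr1"), IRanges::IRanges(c(101, 151), c(200, 250)))
#' mergeSelf(gr)
#' @export
mergeSelf <- function(peaks, gap = 0) {
  stopifnot(gap >= 0)
  GenomicRanges::reduce(.sortGR(peaks), min.gapwidth = gap + 1,
                        ignore.strand = TRUE)
}

#' Count peaks of one set overlapping another
#'
#' Counts intervals of `a` sharing at least `minBp` bases with any interval
#' of `b`. Boolean-symmetric but not count-symmetric.
#'
#' @param a,b `GRanges` peak sets.
#' @param minBp minimum shared bases (>= 1) to call an overlap.
#' @return integer in `[0, length(a)]`.
#' @export
countOverlapping <- function(a, b, minBp = 1) {
  stopifnot(minBp >= 1)
  ab <- .alignSeqlevels(a, b)
  sum(countOverlaps(ab[[1]], ab[[2]], minoverlap = minBp,
                    ignore.strand = TRUE) > 0L)
}

#' Screen candidate cofactor cistromes against an anchor cistrome
#'
#' For each candidate peak set, computes the overlap count and two variants
#' of the overlap coefficient: `coefficient_anchor` divides the number of
#' anchor peaks overlapped by the candidate by the anchor peak count, and
#' `coefficient_merged` divides the number of merged-union peaks containing
#' contributions from both sets by the merged-union peak count. Both sets
#' are self-merged (gap 0) before counting.
#'
#' @param anchor nonempty `GRanges` (e.g. the ER-alpha cistrome).
#' @param candidates named list of `GRanges`, one per candidate factor.
#' @param minBp minimum shared bases to call an overlap.
#' @param sortBy which coefficient orders the rows (descending); ties broken
#'   by factor label.
#' @return data.frame with columns `factor_label`, `overlap_count`,
#'   `coefficient_anchor`, `coefficient_merged`.
#' @export
overlapScreen <- function(anchor, candidates, minBp = 1,
                          sortBy = c("coefficient_anchor", "coefficient_merged")) {
  sortBy <- match.arg(sortBy)
  if (length(anchor) == 0L) stop("anchor peak set is empty")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    stop("candidates must be a named list")
  aM <- mergeSelf(anchor)
  rows <- lapply(names(candidates), function(lab) {
    cM <- mergeSelf(candidates[[lab]])
    oc <- countOverlapping(aM, cM, minBp)
    u <- mergeSelf(c(granges(aM), granges(cM)))
    ab <- .alignSeqlevels(aM, cM)
    both <- sum(countOverlaps(u, ab[[1]], ignore.strand = TRUE) > 0L &
                countOverlaps(u, ab[[2]], ignore.strand = TRUE) > 0L)
    data.frame(factor_label = lab, overlap_count = oc,
               coefficient_anchor = oc / length(aM),
               coefficient_merged = if (length(u)) both / length(u) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out[[sortBy]], out$factor_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
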