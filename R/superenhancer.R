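# Stitch-and-rank super-enhancer identification (ROSE-style): enhancer
# constituents within the stitching distance are merged, regions are ranked
# by summed normalized signal, and the cutoff sits where the tangent slope
# of the scaled signal-vs-rank curve reaches 1.

#' Stitch enhancer constituents into regions
#'
#' Constituents within `stitchGap` bp of each other on one chromosome are
#' merged into a single stitched region. If a TSS table is supplied,
#' constituents overlapping a window of +/- `tssExclusion` bp around any TSS
#' are dropped before stitching (promoter exclusion).
#'
#' @param sites `GRanges` of enhancer constituents.
#' @param stitchGap stitching distance in bp (ROSE default 12500).
#' @param tss optional TSS table as returned by [readTssTable].
#' @param tssExclusion half-width of the promoter-exclusion window (bp).
#' @return `GRanges` of stitched regions with metadata column
#'   `constituentCount`.
#' @export
stitchRegions <- function(sites, stitchGap = 12500, tss = NULL,
                          tssExclusion = 2000) {
  sites <- sort(granges(sites))
  if (!is.null(tss)) {
    prom <- GRanges(tss$chrom,
                    IRanges(pmax(tss$pos + 1 - tssExclusion, 1),
                            tss$pos + 1 + tssExclusion))
    sp <- .alignSeqlevels(sites, prom)
    drop <- countOverlaps(sp[[1]], sp[[2]], ignore.strand = TRUE) > 0L
    if (any(drop))
      message(sum(drop), " promoter-proximal constituent(s) excluded")
    sites <- sites[!drop]
  }
  regions <- mergeSelf(sites, gap = stitchGap)
  mcols(regions)$constituentCount <- countOverlaps(regions, sites,
                                                   ignore.strand = TRUE)
  regions
}

#' Summed constituent signal per stitched region
#'
#' Region signal is the sum of [siteSignal] over the constituents assigned
#' to the region (ROSE-style constituent accounting, not the stitched
#' span), optionally minus the same quantity on a control track, floored
#' at 0.
#'
#' @param regions stitched `GRanges` (from [stitchRegions]).
#' @param constituents the constituent `GRanges`.
#' @param track signal [TagTrack-class] (e.g. H3K27ac).
#' @param control optional control [TagTrack-class] to subtract.
#' @return `regions` with a `signal` metadata column added.
#' @export
stitchedSignal <- function(regions, constituents, track, control = NULL) {
  sig <- siteSignal(constituents, track)
  if (!is.null(control)) sig <- sig - siteSignal(constituents, control)
  rc <- .alignSeqlevels(constituents, regions)
  hit <- findOverlaps(rc[[1]], rc[[2]], select = "first", ignore.strand = TRUE)
  total <- numeric(length(regions))
  ok <- !is.na(hit)
  agg <- tapply(sig[ok], hit[ok], sum)
  total[as.integer(names(agg))] <- agg
  mcols(regions)$signal <- pmax(total, 0)
  regions
}

#' Rank stitched regions by signal and place the tangent-slope-1 cutoff
#'
#' Regions are sorted ascending by signal; rank and signal are both scaled
#' to `[0, 1]` and the cutoff is placed where a line of slope 1 touches the
#' scaled signal-vs-rank curve from below — the index minimizing
#' `scaled_signal - scaled_rank`, which for a convex increasing curve is
#' exactly the point where the tangent slope reaches 1 (on `y = x^2` the
#' touch point is rank 0.5, signal 0.25). This formulation is robust to an
#' isolated low outlier at the bottom of the curve, which would trip a
#' naive first-crossing scan of the discrete slopes. Regions with signal
#' strictly above the cutoff are flagged as super-enhancers; flags are
#' invariant under positive affine rescaling of the signals. A perfectly
#' linear curve has no elbow: the cutoff falls at the maximum signal, the
#' super set is empty and a warning is issued.
#'
#' @param regions `GRanges` with a numeric `signal` metadata column (>= 3
#'   regions, signals not all equal).
#' @return a [StitchRankResult-class].
#' @export
rankAndCut <- function(regions) {
  sig <- mcols(regions)$signal
  if (is.null(sig)) stop("regions must carry a 'signal' metadata column")
  n <- length(regions)
  if (n < 3L) stop("need at least 3 regions to place a cutoff")
  if (diff(range(sig)) == 0) stop("all signals equal: no elbow to cut at")
  ord <- order(sig)
  s <- sig[ord]
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  d <- y - x
  if (diff(range(d)) < 1e-9) {
    # the scaled curve is a straight slope-1 line: no elbow
    warning("signal-vs-rank curve is a straight slope-1 line; empty super set")
    cutoff <- s[n]
  } else {
    # latest index among ties so flat-bottomed minima flag conservatively
    idx <- max(which(d <= min(d) + 1e-12))
    cutoff <- s[idx]
  }
  out <- regions[ord]
  mcols(out)$isSuper <- mcols(out)$signal > cutoff
  new("StitchRankResult", regions = out, cutoffSignal = cutoff,
      nSuper = sum(mcols(out)$isSuper))
}

#' Assign each region to its nearest TSS gene
#'
#' Distance is measured from the region center to the TSS position; ties
#' are broken by gene name (lexicographic). Regions on chromosomes absent
#' from the TSS table are left unassigned (NA) with a message.
#'
#' @param regions `GRanges`.
#' @param tss TSS table from [readTssTable] (columns gene, chrom, pos).
#' @return list with `assignments` (data.frame region_id, gene, distance)
#'   and `uniqueGenes` (count of distinct assigned genes).
#' @export
assignNearestGene <- function(regions, tss) {
  if (!nrow(tss)) stop("TSS table is empty")
  centers <- .siteCenter0(regions)
  chroms <- as.character(seqnames(regions))
  ids <- if (!is.null(names(regions)) && all(nzchar(names(regions))))
    names(regions) else paste0("region_", seq_along(regions))
  gene <- rep(NA_character_, length(regions))
  dist <- rep(NA_real_, length(regions))
  for (ch in unique(chroms)) {
    ri <- which(chroms == ch)
    ti <- which(tss$chrom == ch)
    if (!length(ti)) next
    pos <- tss$pos[ti]
    gn <- tss$gene[ti]
    o <- order(pos, gn)
    pos <- pos[o]; gn <- gn[o]
    for (i in ri) {
      d <- abs(pos - centers[i])
      dmin <- min(d)
      cand <- gn[d == dmin]
      gene[i] <- min(cand)
      dist[i] <- dmin
    }
  }
  if (anyNA(gene))
    message(sum(is.na(gene)), " region(s) on chromosomes absent from the TSS table left unassigned")
  list(assignments = data.frame(region_id = ids, gene = gene,
                                distance = dist, stringsAsFactors = FALSE),
       uniqueGenes = length(unique(gene[!is.na(gene)])))
}
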