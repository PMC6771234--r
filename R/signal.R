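# Binned read-density computation. The density unit throughout is reads per
# 10 million mapped reads per bin (with 100-bp bins, the "10*rpm/bp" unit):
# value = tag count in bin * 1e7 / totalMapped.

# 0-based center of a site; floor midpoint for even-length intervals.
.siteCenter0 <- function(sites) floor((start(sites) - 1 + end(sites)) / 2)

#' Binned normalized read density around site centers
#'
#' Each site is extended to `flank` bp on each side of its center and the
#' window is divided into `2*flank/binWidth` bins (defaults: +/-2 kb, 40
#' bins of 100 bp). The tag count per bin is normalized to reads per 10
#' million mapped reads. Bins are half-open; a tag on a boundary belongs to
#' the bin whose left edge it sits on. Windows running below position 0 are
#' clipped, with out-of-range bins zero-filled.
#'
#' @param sites `GRanges` of sites (rows of the output, in input order).
#' @param track a [TagTrack-class].
#' @param flank half-window in bp; must be divisible by `binWidth`.
#' @param binWidth bin width in bp.
#' @return a [BinnedMatrix-class].
#' @export
binnedDensity <- function(sites, track, flank = 2000, binWidth = 100) {
  stopifnot(is(track, "TagTrack"))
  if (flank %% binWidth != 0) stop("flank must be divisible by binWidth")
  if (track@totalMapped <= 0) stop("totalMapped must be positive")
  nB <- as.integer(2 * flank / binWidth)
  nS <- length(sites)
  ids <- if (!is.null(names(sites)) && all(nzchar(names(sites)))) names(sites)
         else paste0("site_", seq_len(max(nS, 0L)))
  if (nS == 0L)
    return(new("BinnedMatrix",
               values = matrix(numeric(0), 0, nB), binWidth = binWidth,
               flank = flank, siteIds = character(0)))
  c0 <- .siteCenter0(sites)
  binStart0 <- rep(c0 - flank, each = nB) + rep.int(seq_len(nB) - 1L, nS) * binWidth
  chrom <- rep(as.character(seqnames(sites)), each = nB)
  s1 <- binStart0 + 1
  e1 <- binStart0 + binWidth
  clipped <- s1 < 1
  if (any(clipped)) {
    message(sum(clipped), " bin(s) clipped at the chromosome start")
    s1 <- pmax(s1, 1)
  }
  counts <- numeric(nS * nB)
  keep <- e1 >= s1 & e1 >= 1
  if (any(keep)) {
    bins <- GRanges(chrom[keep], IRanges(s1[keep], e1[keep]))
    qt <- .alignSeqlevels(bins, track@tags)
    counts[keep] <- countOverlaps(qt[[1]], qt[[2]], ignore.strand = TRUE)
  }
  vals <- matrix(counts * 1e7 / track@totalMapped, nrow = nS, ncol = nB,
                 byrow = TRUE, dimnames = list(ids[seq_len(nS)], NULL))
  new("BinnedMatrix", values = vals, binWidth = binWidth, flank = flank,
      siteIds = rownames(vals))
}

#' Per-site normalized signal over each site's own span
#'
#' Tag count within each site interval, scaled by 1e7 / totalMapped. Summing
#' the bins of [binnedDensity] over a window matching the site span yields
#' the same total (tag conservation).
#'
#' @param sites `GRanges`.
#' @param track a [TagTrack-class].
#' @return numeric vector, one nonnegative value per site.
#' @export
siteSignal <- function(sites, track) {
  stopifnot(is(track, "TagTrack"))
  qt <- .alignSeqlevels(sites, track@tags)
  countOverlaps(qt[[1]], qt[[2]], ignore.strand = TRUE) * 1e7 / track@totalMapped
}

#' Pearson correlation of two per-site intensity vectors
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with elements `r` and `r_squared`.
#' @export
intensityCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 sites")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- cor(x, y)
  list(r = r, r_squared = r * r)
}

#' Write a binned matrix as TSV
#'
#' Header row gives bin start offsets (bp, relative to the site center).
#'
#' @param x a [BinnedMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBinnedMatrix <- function(x, path) {
  off <- (seq_len(nBins(x)) - 1L) * x@binWidth - x@flank
  df <- data.frame(site_id = x@siteIds, x@values, check.names = FALSE)
  colnames(df) <- c("site_id", off)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
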