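suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(GenomeInfoDb)
})

# canonical sort: lexicographic seqlevels, then position
canonSort <- function(gr) sort(sortSeqlevels(gr))

# Random interval set; dense enough that overlaps are common.
rGR <- function(n, chroms = c("chr1", "chr2"), maxStart = 10000,
                maxWidth = 200) {
  GRanges(sample(chroms, n, replace = TRUE),
          IRanges(sample.int(maxStart, n, replace = TRUE),
                  width = sample.int(maxWidth, n, replace = TRUE)))
}

# All-pairs brute-force oracle for countOverlapping: literal scan over every
# (a, b) pair, independent of any interval-tree machinery.
bruteCountOverlapping <- function(a, b, minBp = 1) {
  ca <- as.character(seqnames(a)); cb <- as.character(seqnames(b))
  sa <- start(a); ea <- end(a); sb <- start(b); eb <- end(b)
  n <- 0L
  for (i in seq_along(a)) {
    j <- which(cb == ca[i])
    if (length(j) &&
        any(pmin(ea[i], eb[j]) - pmax(sa[i], sb[j]) + 1L >= minBp))
      n <- n + 1L
  }
  n
}

# Per-bp covered-base count, the oracle for merge coverage preservation.
coveredBp <- function(gr) {
  sum(width(GenomicRanges::reduce(gr, ignore.strand = TRUE)))
}

# Write a GRanges as BED3 text lines to a temp file.
writeBedLines <- function(gr) {
  path <- tempfile(fileext = ".bed")
  writeLines(paste(as.character(seqnames(gr)), start(gr) - 1, end(gr),
                   sep = "\t"), path)
  path
}

# A TagTrack with exact tag positions (0-based) and a chosen library size.
exactTrack <- function(chrom, pos0, totalMapped = 1e7) {
  tagTrack(chrom, pos0, label = "exact", totalMapped = totalMapped)
}
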