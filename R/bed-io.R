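# BED I/O. All files are 0-based half-open; internally peaks live in
# 1-based closed GRanges, so start gains 1 on the way in and loses 1 on the
# way out. Parsing is line-validated so malformed input errors name the line.

.parseBedFields <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(NULL)
  strsplit(lines, "[ \t]+")
}

#' Read a peak BED file into a sorted GRanges
#'
#' Supports plain BED3, BED5 (column 5 as peak score) and MACS-style
#' narrowPeak (column 7, signalValue, as score). Coordinates are 0-based
#' half-open in the file and converted to the 1-based closed GRanges
#' convention. Extra columns beyond the dialect are ignored; an empty file
#' yields an empty `GRanges`.
#'
#' @param path BED file path.
#' @param dialect one of `"bed3"`, `"bed5"`, `"narrowPeak"`.
#' @return sorted [GenomicRanges::GRanges], with metadata columns `name`
#'   and/or `score` where the dialect provides them.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr2\t10\t60", "chr1\t100\t200"), bed)
#' readPeakBed(bed)
#' @export
readPeakBed <- function(path, dialect = c("bed3", "bed5", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("BED file not found: ", path)
  fields <- .parseBedFields(path)
  if (is.null(fields)) return(GRanges())
  need <- switch(dialect, bed3 = 3L, bed5 = 5L, narrowPeak = 10L)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("malformed BED line %d: fewer than 3 fields", i))
    if (length(f) < need)
      stop(sprintf("malformed BED line %d: %s requires %d fields, found %d",
                   i, dialect, need, length(f)))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e))
      stop(sprintf("malformed BED line %d: non-integer coordinates '%s' '%s'",
                   i, f[2], f[3]))
    if (s < 0)
      stop(sprintf("malformed BED line %d: negative start %s", i, f[2]))
    if (s >= e)
      stop(sprintf("malformed BED line %d: start %s >= end %s", i, f[2], f[3]))
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- as.numeric(vapply(fields, `[`, character(1), 2L))
  end0 <- as.numeric(vapply(fields, `[`, character(1), 3L))
  gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  if (dialect == "bed5") {
    mcols(gr)$name <- vapply(fields, `[`, character(1), 4L)
    mcols(gr)$score <- as.numeric(vapply(fields, `[`, character(1), 5L))
  } else if (dialect == "narrowPeak") {
    mcols(gr)$name <- vapply(fields, `[`, character(1), 4L)
    mcols(gr)$score <- as.numeric(vapply(fields, `[`, character(1), 7L))
  }
  sort(gr)
}

#' Write a GRanges as BED (0-based half-open)
#'
#' Writes BED3, or BED5 when `name`/`score` metadata columns are present.
#'
#' @param gr a `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePeakBed <- function(gr, path) {
  start0 <- format(start(gr) - 1, scientific = FALSE, trim = TRUE)
  end0 <- format(end(gr), scientific = FALSE, trim = TRUE)
  mc <- mcols(gr)
  if (all(c("name", "score") %in% colnames(mc))) {
    out <- paste(as.character(seqnames(gr)), start0, end0, mc$name,
                 format(mc$score, scientific = FALSE, trim = TRUE), sep = "\t")
  } else {
    out <- paste(as.character(seqnames(gr)), start0, end0, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Build a TagTrack from positions
#'
#' @param chrom chromosome per tag.
#' @param pos0 0-based bp position per tag.
#' @param label track label.
#' @param totalMapped total mapped reads; defaults to the number of tags.
#' @return a [TagTrack-class].
#' @export
tagTrack <- function(chrom, pos0, label = "track", totalMapped = NULL) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos0))
  if (length(chrom) != length(pos0)) stop("chrom and pos0 must align")
  if (any(pos0 < 0)) stop("tag positions must be nonnegative")
  if (is.null(totalMapped)) totalMapped <- length(pos0)
  gr <- sort(GenomeInfoDb::sortSeqlevels(GRanges(chrom, IRanges(pos0 + 1, width = 1L))))
  new("TagTrack", label = label, tags = gr, totalMapped = as.numeric(totalMapped))
}

#' Read mapped-tag positions from BED
#'
#' Each BED interval contributes one tag position: its 5' start (plus an
#' optional shift) or its midpoint. Single-position BED (end = start + 1)
#' is the preferred exact input.
#'
#' @param path BED file (>= 3 columns).
#' @param mode `"start"` or `"midpoint"`.
#' @param shift bp added to the position in `"start"` mode (fragment-shift).
#' @param label track label; defaults to the file name.
#' @param totalMapped library size; defaults to the number of tags read.
#' @return a [TagTrack-class].
#' @export
readTagBed <- function(path, mode = c("start", "midpoint"), shift = 0,
                       label = basename(path), totalMapped = NULL) {
  mode <- match.arg(mode)
  gr <- readPeakBed(path, "bed3")
  pos0 <- if (mode == "start") start(gr) - 1 + shift
          else floor((start(gr) - 1 + end(gr)) / 2)
  tagTrack(as.character(seqnames(gr)), pmax(pos0, 0), label = label,
           totalMapped = totalMapped)
}

#' Read a TSS table (gene, chrom, pos, strand) or BED6
#'
#' A 4-column TSV is read as gene/chrom/pos/strand with `pos` a 0-based TSS
#' coordinate. A 6-column file is taken as BED6, with the TSS at the 5' end
#' of the interval given its strand.
#'
#' @param path input file.
#' @return data.frame with columns `gene`, `chrom`, `pos` (0-based), `strand`.
#' @export
readTssTable <- function(path) {
  if (!file.exists(path)) stop("TSS table not found: ", path)
  fields <- .parseBedFields(path)
  if (is.null(fields)) stop("TSS table is empty: ", path)
  n <- lengths(fields)
  if (all(n >= 6L) && !anyNA(suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L))))) {
    chrom <- vapply(fields, `[`, character(1), 1L)
    s0 <- as.numeric(vapply(fields, `[`, character(1), 2L))
    e0 <- as.numeric(vapply(fields, `[`, character(1), 3L))
    gene <- vapply(fields, `[`, character(1), 4L)
    strand <- vapply(fields, `[`, character(1), 6L)
    pos <- ifelse(strand == "-", e0 - 1, s0)
  } else {
    if (any(n < 4L)) stop("TSS table rows need 4 (TSV) or 6 (BED6) fields")
    gene <- vapply(fields, `[`, character(1), 1L)
    chrom <- vapply(fields, `[`, character(1), 2L)
    pos <- as.numeric(vapply(fields, `[`, character(1), 3L))
    strand <- vapply(fields, `[`, character(1), 4L)
    if (anyNA(pos)) stop("non-numeric TSS position in TSV table")
  }
  data.frame(gene = gene, chrom = chrom, pos = pos, strand = strand,
             stringsAsFactors = FALSE)
}

#' Read a patient cohort table
#'
#' Expects a tab-separated file with a header line containing `patient_id`,
#' `time`, `event` (0/1) and one column per gene.
#'
#' @param path TSV file.
#' @return a [CohortTable-class] (E-codes unset).
#' @export
readCohort <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("patient_id", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  genes <- setdiff(colnames(df), need)
  expr <- as.matrix(df[, genes, drop = FALSE])
  rownames(expr) <- df$patient_id
  new("CohortTable", patientIds = as.character(df$patient_id),
      expression = expr, time = as.numeric(df$time),
      event = as.logical(df$event), ecode = character(0),
      geneOrder = character(0))
}

#' Write a cohort table as TSV
#'
#' @param cohort a [CohortTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  df <- data.frame(patient_id = cohort@patientIds, time = cohort@time,
                   event = as.integer(cohort@event), check.names = FALSE)
  df <- cbind(df, as.data.frame(cohort@expression, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
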