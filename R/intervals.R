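# Interval engine: all coordinates inside the package are BED-style,
# 0-based, half-open [start, end). VCF input (1-based, inclusive, END tag)
# is converted at the reader boundary. Abutting intervals do not overlap.

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix (any case) and canonicalizes the sex and
#' mitochondrial chromosomes to `X`, `Y` and `MT`. Annotation resources mix
#' dialects ("chr1", "1", "chrM", "MT"); every reader funnels names through
#' this function so all resources share one namespace.
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalized names.
#' @examples
#' normalize_chrom(c("chr1", "chrX", "M", "mt", "22"))
#' @export
normalize_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  low <- tolower(x)
  x[low == "x"] <- "X"
  x[low == "y"] <- "Y"
  x[low %in% c("m", "mt")] <- "MT"
  x
}

#' Construct a table of genomic intervals
#'
#' Builds the package's internal interval representation: a data frame with
#' columns `chrom`, `start`, `end` (0-based, half-open) and optionally
#' `strand`. Validates the invariants `end > start` and non-empty `chrom`.
#'
#' @param chrom chromosome names (normalized via [normalize_chrom()]).
#' @param start 0-based start positions.
#' @param end exclusive end positions; must satisfy `end > start`.
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`.
#' @return a data frame of class `gintervals`.
#' @export
gintervals <- function(chrom, start, end, strand = NULL) {
  chrom <- normalize_chrom(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start, end must have equal length")
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom must be non-empty")
  if (any(is.na(start)) || any(is.na(end)))
    stop("start/end must be non-missing")
  bad <- which(end <= start)
  if (length(bad))
    stop("end must be > start (half-open, length >= 1); first offender at row ",
         bad[1])
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (!all(strand %in% c("+", "-", ".")))
      stop("strand must be one of '+', '-', '.'")
    out$strand <- strand
  }
  class(out) <- c("gintervals", "data.frame")
  out
}

#' Overlap length between interval pairs
#'
#' Number of shared base pairs between paired intervals, under half-open
#' semantics: abutting intervals (`a$end == b$start`) share zero bases.
#' Intervals on different chromosomes return 0, never an error.
#'
#' @param a,b interval tables (recycled pairwise); data frames with
#'   `chrom`, `start`, `end`.
#' @return integer-valued vector of overlap lengths in bp.
#' @examples
#' a <- gintervals("1", 0, 10); b <- gintervals("1", 5, 15)
#' overlap_bp(a, b)  # 5
#' @export
overlap_bp <- function(a, b) {
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  ov <- pmax(0, ov)
  ov[as.character(a$chrom) != as.character(b$chrom)] <- 0
  ov
}

#' Reciprocal overlap fraction
#'
#' The smaller of the two mutual overlap fractions,
#' `min(overlap/len(a), overlap/len(b))`. Population-frequency matching
#' requires this to be at least 0.5 ("the candidate CNV and the database
#' entry must share at least half of their span").
#'
#' @inheritParams overlap_bp
#' @return numeric vector in \[0, 1\].
#' @examples
#' reciprocal_overlap(gintervals("1", 0, 100), gintervals("1", 50, 150))  # 0.5
#' @export
reciprocal_overlap <- function(a, b) {
  ov <- overlap_bp(a, b)
  pmin(ov / (a$end - a$start), ov / (b$end - b$start))
}

#' Build an overlap index over a set of intervals
#'
#' Wraps the intervals in an interval-tree index (IRanges/GenomicRanges
#' NCList machinery) for fast repeated overlap queries. Rows are stored
#' sorted by (chrom, start, end) so query results have a deterministic
#' order.
#'
#' @param intervals a data frame with `chrom`, `start`, `end` (0-based
#'   half-open); extra columns are carried along.
#' @return an object of class `overlap_index`.
#' @seealso [query_overlaps()]
#' @export
build_index <- function(intervals) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) == 0) {
    obj <- list(intervals = intervals, gr = NULL)
    class(obj) <- "overlap_index"
    return(obj)
  }
  intervals$chrom <- normalize_chrom(intervals$chrom)
  ord <- order(intervals$chrom, intervals$start, intervals$end)
  intervals <- intervals[ord, , drop = FALSE]
  rownames(intervals) <- NULL
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end))
  obj <- list(intervals = intervals, gr = gr)
  class(obj) <- "overlap_index"
  obj
}

#' Query an overlap index
#'
#' Returns the indexed intervals sharing at least `min_bp` bases with the
#' probe, sorted by (start, end). Half-open semantics: an interval whose
#' end equals the probe's start is not returned.
#'
#' @param index an `overlap_index` from [build_index()].
#' @param probe a single-row data frame with `chrom`, `start`, `end`.
#' @param min_bp minimum shared bases (default 1).
#' @return the overlapping rows of the indexed interval table.
#' @export
query_overlaps <- function(index, probe, min_bp = 1L) {
  stopifnot(inherits(index, "overlap_index"), nrow(probe) == 1)
  if (is.null(index$gr)) return(index$intervals)
  pg <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(probe$chrom),
    ranges = IRanges::IRanges(start = probe$start + 1L, end = probe$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(pg, index$gr, minoverlap = min_bp))
  idx <- sort(S4Vectors::subjectHits(hits))
  index$intervals[idx, , drop = FALSE]
}

# Hits of many probes against an index at once; returns a data frame with
# columns query (probe row) and subject (index row). Internal workhorse for
# the feature extractor.
index_hits <- function(index, probes, min_bp = 1L) {
  if (is.null(index$gr) || nrow(probes) == 0)
    return(data.frame(query = integer(), subject = integer()))
  pg <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(probes$chrom),
    ranges = IRanges::IRanges(start = probes$start + 1L, end = probes$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(pg, index$gr, minoverlap = min_bp))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}
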