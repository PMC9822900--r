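#' Do two genomic intervals overlap?
#'
#' 1-based inclusive semantics: intervals on the same chromosome overlap iff
#' `a_start <= b_end && b_start <= a_end`, so a single shared base counts and
#' adjacent intervals do not.
#'
#' @param a_chrom,a_start,a_end first interval (vectors recycle).
#' @param b_chrom,b_start,b_end second interval.
#' @return logical vector.
#' @export
interval_overlaps <- function(a_chrom, a_start, a_end, b_chrom, b_start, b_end) {
  normalize_chrom(a_chrom) == normalize_chrom(b_chrom) &
    a_start <= b_end & b_start <= a_end
}

# data.frame (chrom/start/end[/strand]) -> GRanges. All interval joins in the
# package run through GenomicRanges; closed 1-based IRanges coordinates are
# exactly the internal model, so no shifting is needed.
as_granges <- function(df) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(.CHROMS)))
  }
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = .CHROMS),
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = if ("strand" %in% names(df)) {
      ifelse(df$strand %in% c("+", "-"), df$strand, "*")
    } else "*",
    seqinfo = GenomeInfoDb::Seqinfo(.CHROMS)
  )
}

#' Which query intervals are overlapped by at least one subject interval?
#'
#' Any-overlap (>= 1 shared base) by default; `min_reciprocal > 0` requires
#' the shared span to cover at least that fraction of BOTH intervals.
#'
#' @param query,subject data.frames with `chrom`, `start`, `end`.
#' @param min_reciprocal reciprocal overlap fraction in `[0, 1]`; 0 means any
#'   overlap.
#' @return logical vector along the rows of `query`.
#' @export
overlaps_any <- function(query, subject, min_reciprocal = 0) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  q <- as_granges(query)
  s <- as_granges(subject)
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  if (min_reciprocal > 0 && length(hits) > 0) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    inter <- pmin(query$end[qi], subject$end[si]) -
      pmax(query$start[qi], subject$start[si]) + 1
    wq <- query$end[qi] - query$start[qi] + 1
    ws <- subject$end[si] - subject$start[si] + 1
    keep <- inter >= min_reciprocal * wq & inter >= min_reciprocal * ws
    hits <- hits[keep]
  }
  seq_len(nrow(query)) %in% S4Vectors::queryHits(hits)
}
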