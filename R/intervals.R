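# Interval algebra on 0-based half-open coordinates.
#
# Intervals are carried as GRanges. GRanges/IRanges are 1-based closed, so a
# half-open interval [start, end) maps to IRanges(start + 1, end); all public
# constructors and accessors speak 0-based half-open, conversion happens once
# at the boundary. Abutting intervals (end == start) never overlap.

#' Build an interval set from 0-based half-open coordinates
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; requires
#'   `0 <= start < end`.
#' @param strand strand, one of `"+"`, `"-"`, `"."` (unstranded); `"."` is
#'   stored as `"*"`.
#' @param name,score optional per-interval identifier and numeric score.
#' @return A `GRanges` holding the intervals.
#' @export
intervals <- function(chrom, start, end, strand = ".", name = NULL,
                      score = NULL) {
  if (length(chrom) == 0L) return(GenomicRanges::GRanges())
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start) | is.na(end)))
    stop("interval coordinates must be non-missing numbers")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop(sprintf("invalid interval: start (%s) >= end (%s)",
                 format(start[bad], scientific = FALSE),
                 format(end[bad], scientific = FALSE)))
  }
  if (any(!nzchar(chrom))) stop("chrom must be non-empty")
  strand <- ifelse(strand == ".", "*", strand)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1, end),
                               strand = strand)
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- as.character(name)
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- as.numeric(score)
  gr
}

#' 0-based starts / half-open ends of an interval set
#' @param x a `GRanges`.
#' @return numeric vector.
#' @export
iv_start <- function(x) GenomicRanges::start(x) - 1

#' @rdname iv_start
#' @export
iv_end <- function(x) as.numeric(GenomicRanges::end(x))

#' Normalize an interval set
#'
#' Sorts by (chrom, start) and optionally merges overlapping and book-ended
#' intervals. With `merge_dist = 0` (default when merging) abutting intervals
#' are merged; `merge_dist = NULL` leaves overlaps untouched.
#'
#' @param x a `GRanges`.
#' @param merge_dist non-negative merge distance in bp, or `NULL` to sort
#'   only.
#' @param ignore_strand merge across strands (default `TRUE`).
#' @return sorted (and possibly merged) `GRanges`.
#' @export
normalize_intervals <- function(x, merge_dist = 0, ignore_strand = TRUE) {
  x <- GenomicRanges::sort(x, ignore.strand = ignore_strand)
  if (is.null(merge_dist)) return(x)
  if (merge_dist < 0) stop("merge_dist must be >= 0")
  GenomicRanges::reduce(x, min.gapwidth = merge_dist + 1L,
                        ignore.strand = ignore_strand)
}

#' Strand-aware flank of a position or interval
#'
#' The upstream flank of a plus-strand feature at position `pos` is
#' `[pos - length, pos)`, clipped at the chromosome start; strand-mirrored
#' for minus-strand features. For an interval, flanks are taken from the
#' strand-aware 5' (upstream) or 3' (downstream) boundary.
#'
#' @param chrom chromosome name.
#' @param pos 0-based anchor position (for a point anchor), or pass
#'   `start`/`end` for an interval anchor.
#' @param length flank length in bp (> 0).
#' @param side `"upstream"` or `"downstream"`.
#' @param strand `"+"`, `"-"` or `"."` (treated as `"+"`).
#' @param start,end optional 0-based half-open interval anchor.
#' @return single-interval `GRanges`.
#' @export
flank_interval <- function(chrom, pos = NULL, length, side = c("upstream",
                           "downstream"), strand = "+", start = NULL,
                           end = NULL) {
  side <- match.arg(side)
  if (length <= 0) stop("flank length must be > 0")
  if (strand == "." || strand == "*") strand <- "+"
  if (is.null(pos)) {
    if (is.null(start) || is.null(end))
      stop("provide either pos or start/end")
    # anchor at the boundary the flank grows away from
    pos <- if (side == "upstream") {
      if (strand == "+") start else end
    } else {
      if (strand == "+") end else start
    }
  }
  grows_left <- (side == "upstream") == (strand == "+")
  if (grows_left) {
    s <- max(0, pos - length); e <- pos
  } else {
    s <- pos; e <- pos + length
  }
  if (s >= e)
    stop("flank collapsed to zero width at chromosome start")
  intervals(chrom, s, e, strand = strand)
}

#' Overlap-filter one interval set by another
#'
#' Returns the members of `a` that overlap `b`. With `min_frac`, the summed
#' overlap must cover at least that fraction of the `a` interval (and, when
#' `reciprocal`, at least that fraction of some single overlapping `b`
#' interval as well, mirroring `bedtools intersect -f -r`).
#'
#' @param a,b `GRanges`.
#' @param min_frac `NULL`, or a fraction in (0, 1].
#' @param reciprocal also require `min_frac` of the `b` interval.
#' @param ignore_strand ignore strand when overlapping (default `TRUE`).
#' @return the qualifying subset of `a`.
#' @export
intersect_sets <- function(a, b, min_frac = NULL, reciprocal = FALSE,
                           ignore_strand = TRUE) {
  if (!is.null(min_frac) && (min_frac <= 0 || min_frac > 1))
    stop("min_frac must be in (0, 1]")
  hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = ignore_strand)
  if (length(hits) == 0L) return(a[0])
  if (is.null(min_frac)) return(a[unique(S4Vectors::queryHits(hits))])
  ov <- GenomicRanges::pintersect(a[S4Vectors::queryHits(hits)],
                                  b[S4Vectors::subjectHits(hits)],
                                  ignore.strand = ignore_strand)
  wo <- GenomicRanges::width(ov)
  ok_a <- wo >= min_frac * GenomicRanges::width(a)[S4Vectors::queryHits(hits)]
  keep <- ok_a
  if (reciprocal) {
    ok_b <- wo >=
      min_frac * GenomicRanges::width(b)[S4Vectors::subjectHits(hits)]
    keep <- ok_a & ok_b
  }
  a[sort(unique(S4Vectors::queryHits(hits)[keep]))]
}

#' Per-base union / difference of interval sets
#'
#' `merge_sets` merges overlapping and book-ended intervals within one set;
#' `subtract_sets` removes every base of `b` from `a`. Both ignore strand.
#'
#' @param a,b `GRanges`.
#' @param merge_dist merge distance for `merge_sets` (0 merges abutting).
#' @return `GRanges`.
#' @export
merge_sets <- function(a, merge_dist = 0) {
  normalize_intervals(a, merge_dist = merge_dist, ignore_strand = TRUE)
}

#' @rdname merge_sets
#' @export
subtract_sets <- function(a, b) {
  GenomicRanges::setdiff(normalize_intervals(a),
                         normalize_intervals(b),
                         ignore.strand = TRUE)
}

#' Base-pair intersection of two interval sets
#'
#' The per-base common footprint (`bedtools intersect` on merged inputs),
#' strand-ignorant.
#' @param a,b `GRanges`.
#' @return `GRanges`.
#' @export
intersection_footprint <- function(a, b) {
  GenomicRanges::intersect(normalize_intervals(a), normalize_intervals(b),
                           ignore.strand = TRUE)
}

#' Total interval length in bp
#' @param x `GRanges` (merged internally).
#' @return numeric scalar.
#' @export
total_width <- function(x) {
  sum(as.numeric(GenomicRanges::width(normalize_intervals(x))))
}
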