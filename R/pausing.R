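# RNA-polymerase pausing from run-on (GRO-seq) or RNAPII ChIP coverage.
#
# The pausing index is the quotient of binned mean signal over a feature
# (TFBS or flank) and over the whole transcribed domain. Partial end bins
# are length-weighted, so the binned mean equals the plain per-base mean
# and the index is invariant under bin-size changes on piecewise-smooth
# tracks and under global rescaling of the track.

#' Pausing index of a feature within a transcribed domain
#'
#' @param track coverage track (`RleList` from [read_bedgraph()]).
#' @param feature,domain single-interval `GRanges`; `feature` must lie
#'   inside `domain`.
#' @param bin_size bin width in bp (default 50; partial end bins are
#'   length-weighted).
#' @return list: `pausing_index`, `feature_mean`, `domain_mean`,
#'   `bin_size`.
#' @export
pausing_index <- function(track, feature, domain, bin_size = 50) {
  fc <- as.character(GenomicRanges::seqnames(feature))
  dc <- as.character(GenomicRanges::seqnames(domain))
  if (fc != dc || iv_start(feature) < iv_start(domain) ||
      iv_end(feature) > iv_end(domain))
    stop("feature must lie within the domain")
  fmean <- coverage_mean(track, fc, iv_start(feature), iv_end(feature))
  dmean <- coverage_mean(track, dc, iv_start(domain), iv_end(domain))
  if (dmean == 0) stop("pausing index undefined: zero domain signal")
  list(pausing_index = fmean / dmean, feature_mean = fmean,
       domain_mean = dmean, bin_size = bin_size)
}

#' Anchor-centred average signal profile
#'
#' Averages the coverage in windows of `2 * half_width` centred on each
#' anchor, binned; minus-strand anchors are reversed so that downstream is
#' always to the right.
#'
#' @param track coverage track (`RleList`).
#' @param anchors data.frame with `chrom`, `pos` (0-based) and optional
#'   `strand`.
#' @param half_width half window size in bp (default 1000).
#' @param bin bin width in bp (default 25).
#' @return numeric vector of `2 * half_width / bin` mean values.
#' @export
metaprofile <- function(track, anchors, half_width = 1000, bin = 25) {
  if (nrow(anchors) < 1L) stop("need >= 1 anchor")
  nbin <- as.integer(2 * half_width / bin)
  acc <- numeric(nbin)
  for (i in seq_len(nrow(anchors))) {
    lo <- anchors$pos[i] - half_width
    vals <- vapply(seq_len(nbin), function(b)
      coverage_mean(track, anchors$chrom[i],
                    max(0, lo + (b - 1L) * bin), max(1, lo + b * bin)), 0)
    st <- if ("strand" %in% names(anchors)) anchors$strand[i] else "+"
    if (st == "-") vals <- rev(vals)
    acc <- acc + vals
  }
  acc / nrow(anchors)
}

#' Correlation of pausing indices with TF ChIP signal
#'
#' Pearson correlation across matched sites; a negative value is the
#' signature of polymerase pausing occluding TF binding.
#'
#' @param pausing numeric pausing indices.
#' @param tf_signal numeric ChIP intensities for the same sites.
#' @return Pearson r.
#' @export
pausing_tf_correlation <- function(pausing, tf_signal) {
  if (length(pausing) != length(tf_signal))
    stop("pausing and tf_signal must be matched")
  if (length(pausing) < 3L) stop("need >= 3 sites")
  stats::cor(pausing, tf_signal)
}
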