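# Allele-specific expression and enhancer-promoter loop analysis.

#' Exact two-sided binomial test for allelic imbalance at one SNV
#'
#' The two-sided p-value at p = 0.5 sums the probabilities of all outcomes
#' whose point mass does not exceed that of the observed count (the
#' standard exact two-sided rule; deterministic). Sites flagged as RNA
#' editing must be excluded upstream and are an error here.
#'
#' @param ref_count,alt_count non-negative read counts (sum >= 1).
#' @param alpha significance level (default 0.05).
#' @param masked is the site in the supplied RNA-editing mask?
#' @return list: `p_binom`, `significant`, `allele_with_eotr` (`"ref"`,
#'   `"alt"` or `"none"`: the over-expressed allele when significant).
#' @export
ase_test <- function(ref_count, alt_count, alpha = 0.05, masked = FALSE) {
  if (masked) stop("site is in the RNA-editing mask; exclude upstream")
  if (ref_count < 0 || alt_count < 0) stop("counts must be >= 0")
  n <- ref_count + alt_count
  if (n < 1L) stop("ref_count + alt_count must be >= 1")
  pm <- stats::dbinom(0:n, n, 0.5)
  p <- min(1, sum(pm[pm <= pm[ref_count + 1L] * (1 + 1e-7)]))
  sig <- p < alpha
  list(p_binom = p, significant = sig,
       allele_with_eotr = if (!sig) "none" else
         if (ref_count > alt_count) "ref" else "alt")
}

#' Allelic enhancer-activity contrast
#'
#' Per-locus fold-change class of H3K27ac occupancy on the EOTr-carrying
#' allele versus the other allele, using the differential-call rules
#' (|L2FC| > 1.5 and BH-adjusted p < 0.05). Loci missing counts on either
#' allele are skipped with a warning.
#'
#' @param counts_eotr_allele,counts_other_allele matrices (loci x
#'   replicates) of H3K27ac counts within the locus' major H3K4me1 peak.
#' @param l2fc_threshold,alpha,n_perm,seed forwarded to
#'   [differential_call()].
#' @return data.frame: `locus`, `l2fc`, `q`, `fc_class` (class of the
#'   EOTr+ allele: -1 down, 0 unchanged, +1 up).
#' @export
allelic_activity_contrast <- function(counts_eotr_allele,
                                      counts_other_allele,
                                      l2fc_threshold = 1.5, alpha = 0.05,
                                      n_perm = 1000, seed = 1) {
  common <- intersect(rownames(counts_eotr_allele),
                      rownames(counts_other_allele))
  dropped <- setdiff(union(rownames(counts_eotr_allele),
                           rownames(counts_other_allele)), common)
  if (length(dropped))
    warning("skipping loci missing one allele: ",
            paste(dropped, collapse = ", "))
  # allele layers come from one library: a genuine genome-wide activity
  # shift between alleles must not be scaled away
  res <- differential_call(counts_eotr_allele[common, , drop = FALSE],
                           counts_other_allele[common, , drop = FALSE],
                           l2fc_threshold = l2fc_threshold, alpha = alpha,
                           n_perm = n_perm, seed = seed, scale = FALSE,
                           library_sizes = rep(1e6, ncol(counts_eotr_allele) +
                                                 ncol(counts_other_allele)))
  data.frame(locus = res$feature, l2fc = res$l2fc, q = res$q,
             fc_class = res$fc_class, stringsAsFactors = FALSE)
}

#' Classify enhancer-anchored loops by distal-anchor marks
#'
#' For each interaction with at least one anchor in an enhancer, the distal
#' anchor is classified `promoter` when it overlaps H3K4me3, `insulator`
#' when it overlaps CTCF without H3K4me3, and `other` otherwise. The
#' classification is symmetric under swapping the anchors. When promoter
#' state calls are supplied, the overlapped promoter's state is attached.
#'
#' @param loops data.frame from [read_bedpe()].
#' @param enhancers `GRanges` (or state-call data.frame) of enhancer
#'   domains.
#' @param h3k4me3,ctcf `GRanges` peak sets.
#' @param promoter_states optional data.frame from [classify_promoters()].
#' @return `loops` with columns `enhancer_anchor` ("A"/"B"/"none"),
#'   `distal_class`, `promoter_state`, `intra_chromosomal`.
#' @export
assign_loops <- function(loops, enhancers, h3k4me3, ctcf,
                         promoter_states = NULL) {
  enh <- if (is.data.frame(enhancers)) states_to_granges(enhancers)
  else enhancers
  k4 <- normalize_intervals(h3k4me3)
  ct <- normalize_intervals(ctcf)
  anchA <- intervals(loops$chromA, loops$startA, loops$endA)
  anchB <- intervals(loops$chromB, loops$startB, loops$endB)
  inA <- IRanges::overlapsAny(anchA, enh, ignore.strand = TRUE)
  inB <- IRanges::overlapsAny(anchB, enh, ignore.strand = TRUE)
  classify <- function(anchor) {
    has_k4 <- IRanges::overlapsAny(anchor, k4, ignore.strand = TRUE)
    has_ct <- IRanges::overlapsAny(anchor, ct, ignore.strand = TRUE)
    ifelse(has_k4, "promoter", ifelse(has_ct, "insulator", "other"))
  }
  clA <- classify(anchA); clB <- classify(anchB)
  loops$enhancer_anchor <- ifelse(inA, "A", ifelse(inB, "B", "none"))
  loops$distal_class <- ifelse(inA, clB, ifelse(inB, clA, NA_character_))
  loops$promoter_state <- NA_character_
  if (!is.null(promoter_states) && nrow(promoter_states)) {
    pr <- states_to_granges(promoter_states)
    pick <- function(anchor) {
      hits <- GenomicRanges::findOverlaps(anchor, pr, ignore.strand = TRUE)
      out <- rep(NA_character_, length(anchor))
      out[S4Vectors::queryHits(hits)] <-
        S4Vectors::mcols(pr)$name[S4Vectors::subjectHits(hits)]
      out
    }
    loops$promoter_state <- ifelse(inA, pick(anchB), ifelse(inB,
                                                            pick(anchA),
                                                            NA))
  }
  loops$intra_chromosomal <- loops$chromA == loops$chromB
  loops
}

#' Chi-squared contrast of loop counts between allele/locus classes
#'
#' Tests whether loops are distributed across two enhancer groups in
#' proportion to group size, via a 2x2 table of (loop count, enhancer
#' count) per group.
#'
#' @param loops_a,loops_b loop counts in the two groups.
#' @param n_enhancers_a,n_enhancers_b enhancer counts per group.
#' @return list from [chi2_counts()] plus the `counts` table.
#' @export
loop_count_contrast <- function(loops_a, loops_b, n_enhancers_a,
                                n_enhancers_b) {
  tab <- matrix(c(loops_a, loops_b, n_enhancers_a, n_enhancers_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("loops", "enhancers"), c("a", "b")))
  c(chi2_counts(tab), list(counts = tab))
}

#' Intra- to inter-chromosomal contact ratio
#'
#' @param loops data.frame with `chromA`, `chromB` (or an
#'   `intra_chromosomal` column).
#' @return list: `ratio` (Inf when no inter-chromosomal loop), `intra`,
#'   `inter`, `infinite` flag.
#' @export
contact_ratio <- function(loops) {
  intra <- if ("intra_chromosomal" %in% names(loops))
    sum(loops$intra_chromosomal) else sum(loops$chromA == loops$chromB)
  inter <- nrow(loops) - intra
  list(ratio = if (inter == 0) Inf else intra / inter,
       intra = intra, inter = inter, infinite = inter == 0)
}
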