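# Chromatin-state classification from histone-mark peak combinations.
#
# Enhancer candidates are the merged base-pair intersection of H3K4me1 and
# p300 footprints; acetylation (H3K27ac and/or H3K9ac) separates active from
# poised. Promoters require all of H3K4me3, H3K4me2, H3K27ac and RNAPII to
# be active; H3K4me3 together with H3K27me3 marks a poised promoter and
# dominates when both rules fire. eRNA domains are acetylated enhancer
# candidates devoid of H3K36me3 and H3K4me3. Overlap means >= 1 bp unless a
# fraction is configured.

state_call <- function(gr, state, evidence) {
  if (length(gr) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), state = character(),
                      evidence = character(), direction = character(),
                      stringsAsFactors = FALSE))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = iv_start(gr), end = iv_end(gr),
             state = state, evidence = evidence, direction = ".",
             stringsAsFactors = FALSE)
}

states_to_granges <- function(calls) {
  if (nrow(calls) == 0L) return(GenomicRanges::GRanges())
  intervals(calls$chrom, calls$start, calls$end,
            strand = calls$direction %||% ".",
            name = calls$state)
}

#' Consensus peaks across biological replicates by base-pair voting
#'
#' A base belongs to the consensus when covered by at least `min_support`
#' replicate peak sets.
#'
#' @param replicates list of `GRanges`, one per replicate.
#' @param min_support minimum number of supporting replicates.
#' @return `GRanges` of consensus intervals.
#' @export
consensus_peaks <- function(replicates, min_support = 2L) {
  if (length(replicates) < 1L) stop("need >= 1 replicate")
  if (min_support > length(replicates))
    stop("min_support exceeds the number of replicates")
  pooled <- do.call(c, lapply(replicates, function(r)
    GenomicRanges::granges(normalize_intervals(r))))
  cov <- GenomicRanges::coverage(pooled)
  hits <- IRanges::slice(cov, lower = min_support, rangesOnly = TRUE)
  gr <- GenomicRanges::GRanges(hits)
  GenomicRanges::granges(gr)
}

#' Classify enhancer domains as active or poised
#'
#' Candidate domains are the merged H3K4me1 and p300 common footprint;
#' a candidate overlapping H3K27ac or H3K9ac is active, otherwise poised.
#'
#' @param h3k4me1,p300,h3k27ac,h3k9ac `GRanges` peak sets.
#' @param min_frac optional overlap fraction required of the candidate.
#' @return data.frame of state calls (chrom, start, end, state, evidence).
#' @export
classify_enhancers <- function(h3k4me1, p300, h3k27ac, h3k9ac,
                               min_frac = NULL) {
  cand <- merge_sets(intersection_footprint(h3k4me1, p300))
  if (length(cand) == 0L) return(state_call(cand, character(), character()))
  acet <- merge_sets(c(GenomicRanges::granges(normalize_intervals(h3k27ac)),
                       GenomicRanges::granges(normalize_intervals(h3k9ac))))
  active <- if (is.null(min_frac)) IRanges::overlapsAny(cand, acet) else
    seq_along(cand) %in% match(
      as.character(intersect_sets(cand, acet, min_frac = min_frac)),
      as.character(cand))
  ev27 <- IRanges::overlapsAny(cand, normalize_intervals(h3k27ac))
  ev9 <- IRanges::overlapsAny(cand, normalize_intervals(h3k9ac))
  evidence <- paste0("H3K4me1,p300",
                     ifelse(ev27, ",H3K27ac", ""),
                     ifelse(ev9, ",H3K9ac", ""))
  state_call(cand, ifelse(active, "enhancer_active", "enhancer_poised"),
             evidence)
}

#' Classify promoter domains as active or poised
#'
#' Active promoters carry H3K4me3, H3K4me2, H3K27ac and RNAPII together;
#' H3K4me3 overlapping H3K27me3 is poised, and poised dominates when both
#' rules fire.
#'
#' @param h3k4me3,h3k4me2,h3k27ac,rnapii,h3k27me3 `GRanges` peak sets.
#' @return data.frame of state calls.
#' @export
classify_promoters <- function(h3k4me3, h3k4me2, h3k27ac, rnapii,
                               h3k27me3) {
  base <- merge_sets(h3k4me3)
  if (length(base) == 0L) return(state_call(base, character(), character()))
  has <- function(s) IRanges::overlapsAny(base, normalize_intervals(s))
  active <- has(h3k4me2) & has(h3k27ac) & has(rnapii)
  poised <- has(h3k27me3)
  state <- rep("none", length(base))
  state[active] <- "promoter_active"
  state[poised] <- "promoter_poised"  # poised dominance
  evidence <- paste0("H3K4me3",
                     ifelse(has(h3k4me2), ",H3K4me2", ""),
                     ifelse(has(h3k27ac), ",H3K27ac", ""),
                     ifelse(has(rnapii), ",RNAPII", ""),
                     ifelse(poised, ",H3K27me3", ""))
  keep <- state != "none"
  state_call(base[keep], state[keep], evidence[keep])
}

#' Identify eRNA-producing enhancer domains
#'
#' Qualifying domains carry all four positive marks (H3K4me1, H3K27ac,
#' H3K9ac, p300) and neither H3K36me3 nor H3K4me3. Transcription direction
#' is the majority strand of intersecting transcripts and CAGE clusters,
#' `"."` on a tie or without evidence.
#'
#' @param h3k4me1,h3k27ac,h3k9ac,p300,h3k36me3,h3k4me3 `GRanges` peak sets.
#' @param transcripts optional `transcript_set` of expressed cDNA contigs.
#' @param cage optional `GRanges` of CAGE clusters (stranded).
#' @return data.frame of state calls with a `direction` column.
#' @export
identify_erna_domains <- function(h3k4me1, h3k27ac, h3k9ac, p300,
                                  h3k36me3, h3k4me3, transcripts = NULL,
                                  cage = NULL) {
  cand <- merge_sets(intersection_footprint(h3k4me1, p300))
  if (length(cand) == 0L) return(state_call(cand, character(), character()))
  has <- function(s) IRanges::overlapsAny(cand, normalize_intervals(s))
  ok <- has(h3k27ac) & has(h3k9ac) & !has(h3k36me3) & !has(h3k4me3)
  cand <- cand[ok]
  calls <- state_call(cand, "erna_domain",
                      "H3K4me1,H3K27ac,H3K9ac,p300")
  if (nrow(calls) == 0L) return(calls)
  ev <- GenomicRanges::GRanges()
  if (!is.null(transcripts))
    ev <- suppressWarnings(c(ev, transcript_spans(transcripts)))
  if (!is.null(cage))
    ev <- suppressWarnings(c(ev, GenomicRanges::granges(cage)))
  if (length(ev)) {
    hits <- GenomicRanges::findOverlaps(cand, ev, ignore.strand = TRUE)
    st <- as.character(GenomicRanges::strand(ev))
    for (i in seq_along(cand)) {
      s <- st[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
      np <- sum(s == "+"); nm <- sum(s == "-")
      calls$direction[i] <- if (np > nm) "+" else if (nm > np) "-" else "."
    }
  }
  calls
}

#' Heterochromatin flag for a region
#'
#' TRUE when the region overlaps an H3K27me3 (representative
#' heterochromatin mark) peak by >= 1 bp; abutting peaks do not overlap.
#'
#' @param region single-interval `GRanges`.
#' @param h3k27me3 `GRanges` peak set.
#' @return logical.
#' @export
heterochromatin_flag <- function(region, h3k27me3) {
  any(IRanges::overlapsAny(region, normalize_intervals(h3k27me3)))
}
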