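# The EOTr detection cascade: from raw transcript models through location
# annotation, coding-potential filtering, chromatin-signature filters
# (H3K36me3 body + H3K4me3 promoter), enhancer overlap, CAGE/polyA
# evidence and TFBS intersection, to the final occlusion call.

# ---- coding potential -------------------------------------------------

# Fickett TESTCODE lookup tables (position and content parameters with
# their weights), as used by the classic algorithm.
.fickett <- list(
  pos_para = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0),
  con_para = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0),
  pos_prob = list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
  pos_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
  con_prob = list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)),
  con_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14))

#' Fickett TESTCODE score of a nucleotide sequence
#' @param sequence A/C/G/T sequence (sense strand).
#' @return numeric score (higher = more coding-like).
#' @export
fickett_score <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  s <- s[s %in% BASES]
  n <- length(s)
  if (n < 2L) return(0)
  total <- 0
  for (b in BASES) {
    inframe <- vapply(0:2, function(f) sum(s[seq(1 + f, n, by = 3)] == b),
                      0)
    posval <- max(inframe) / (min(inframe) + 1)
    conval <- sum(s == b) / n
    pi <- which(posval >= .fickett$pos_para)[1L]
    ci <- which(conval >= .fickett$con_para)[1L]
    total <- total + .fickett$pos_prob[[b]][pi] * .fickett$pos_weight[b] +
      .fickett$con_prob[[b]][ci] * .fickett$con_weight[b]
  }
  unname(total)
}

#' Longest open reading frame on the sense strand
#' @param sequence A/C/G/T sequence.
#' @return list: `length` (nt, 0 if none), `start` (0-based, NA if none),
#'   `orf` (sequence or "").
#' @export
longest_orf <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  codons_at <- function(off) {
    substring(s, seq(1 + off, n - 2, by = 3), seq(3 + off, n, by = 3))
  }
  best <- list(length = 0, start = NA_real_, orf = "")
  for (f in 0:2) {
    if (n - f < 6L) next
    cods <- codons_at(f)
    starts <- which(cods == "ATG")
    stops <- which(cods %in% c("TAA", "TAG", "TGA"))
    for (st in starts) {
      sp <- stops[stops > st]
      if (length(sp) == 0L) next
      len <- (sp[1L] - st + 1L) * 3L
      if (len > best$length) {
        pos0 <- f + (st - 1L) * 3L
        best <- list(length = len, start = pos0,
                     orf = substr(s, pos0 + 1L, pos0 + len))
      }
      # only the first in-frame start before each stop can extend further
    }
  }
  best
}

.hexamers <- function(sequence, step = 3L) {
  n <- nchar(sequence)
  if (n < 6L) return(character())
  substring(sequence, seq(1L, n - 5L, by = step),
            seq(6L, n, by = step))
}

hexamer_table <- function(seqs, use_orf = FALSE, pseudocount = 1) {
  hx <- unlist(lapply(toupper(seqs), function(s) {
    if (use_orf) {
      o <- longest_orf(s)
      if (o$length >= 6) s <- o$orf
    }
    .hexamers(s)
  }))
  all_h <- sort(do.call(paste0, expand.grid(BASES, BASES, BASES, BASES,
                                            BASES, BASES)))
  counts <- table(factor(hx, levels = all_h)) + pseudocount
  log(as.numeric(counts) / sum(counts)) |> setNames(all_h)
}

#' Hexamer log-likelihood ratio of a sequence
#'
#' Mean log ratio of in-frame hexamer frequencies under the coding model
#' versus the noncoding model, computed along the longest ORF when one
#' exists, else along the whole sequence.
#'
#' @param sequence A/C/G/T sequence.
#' @param model a `cp_model` (see [train_cp()]).
#' @return numeric LLR.
#' @export
hexamer_llr <- function(sequence, model) {
  s <- toupper(sequence)
  o <- longest_orf(s)
  if (o$length >= 6) s <- o$orf
  hx <- .hexamers(s)
  hx <- hx[hx %in% names(model$hex_coding)]
  if (length(hx) == 0L) return(0)
  mean(model$hex_coding[hx] - model$hex_noncoding[hx])
}

cp_features <- function(sequence, model) {
  if (nchar(sequence) < 60L)
    stop("coding potential undefined for sequences < 60 nt")
  o <- longest_orf(sequence)
  data.frame(orf_len = o$length,
             orf_cov = o$length / nchar(sequence),
             fickett = fickett_score(sequence),
             hexamer = hexamer_llr(sequence, model))
}

#' Train the coding-potential model
#'
#' Logistic regression of coding status on four sequence features: longest
#' ORF length, ORF coverage, Fickett TESTCODE score, and the hexamer
#' log-likelihood ratio (coding vs noncoding hexamer tables estimated from
#' the training sets).
#'
#' @param coding_seqs,noncoding_seqs character vectors of training
#'   sequences (>= 60 nt each).
#' @return object of class `cp_model`.
#' @export
train_cp <- function(coding_seqs, noncoding_seqs) {
  model <- list(hex_coding = hexamer_table(coding_seqs, use_orf = TRUE),
                hex_noncoding = hexamer_table(noncoding_seqs))
  feats <- rbind(
    do.call(rbind, lapply(coding_seqs, cp_features, model = model)),
    do.call(rbind, lapply(noncoding_seqs, cp_features, model = model)))
  feats$y <- rep(c(1L, 0L), c(length(coding_seqs), length(noncoding_seqs)))
  fit <- suppressWarnings(stats::glm(
    y ~ orf_len + orf_cov + fickett + hexamer,
    data = feats, family = stats::binomial()))
  model$glm <- fit
  class(model) <- "cp_model"
  model
}

#' Coding potential of a transcript sequence
#'
#' Probability that the sequence is protein-coding under the trained
#' logistic model; scores at or above `coding_cutoff` (default 0.364) are
#' classified coding.
#'
#' @param sequence A/C/G/T sequence (>= 60 nt).
#' @param model a `cp_model`.
#' @return numeric CP in [0, 1].
#' @export
coding_potential <- function(sequence, model) {
  f <- cp_features(sequence, model)
  unname(suppressWarnings(
    stats::predict(model$glm, newdata = f, type = "response")))
}

#' @rdname coding_potential
#' @param cp numeric CP score(s).
#' @param coding_cutoff inclusive coding boundary.
#' @return `is_coding`: logical.
#' @export
is_coding <- function(cp, coding_cutoff = 0.364) cp >= coding_cutoff

# ---- cascade stages ---------------------------------------------------

new_records <- function(ts) {
  data.frame(id = ts$tx$id, chrom = ts$tx$chrom, strand = ts$tx$strand,
             start = ts$tx$start, end = ts$tx$end, tss = ts$tx$tss,
             tts = ts$tx$tts, polyadenylated = ts$tx$polyadenylated,
             spliced = ts$tx$spliced, cpm = ts$tx$cpm,
             location = NA_character_, cp_score = NA_real_,
             cage_peak = NA_real_, is_eotr = FALSE,
             stringsAsFactors = FALSE)
}

#' Annotate transcript location relative to known gene models
#'
#' Transcripts with any exon overlapping a known exon are `excluded`;
#' remaining transcripts are `intronic` when the majority of their span
#' lies within known gene bodies and `intergenic` otherwise.
#'
#' @param ts candidate `transcript_set`.
#' @param known_genes `transcript_set` of annotated genes (exon models).
#' @return candidate-record data.frame with a `location` column.
#' @export
annotate_location <- function(ts, known_genes) {
  rec <- new_records(ts)
  known_ex <- merge_sets(unlist(known_genes$exons))
  known_span <- merge_sets(transcript_spans(known_genes))
  spans <- transcript_spans(ts)
  exonic_hit <- vapply(rec$id, function(id)
    any(IRanges::overlapsAny(ts$exons[[id]], known_ex,
                             ignore.strand = TRUE)), TRUE)
  inside_bp <- vapply(seq_len(nrow(rec)), function(i) {
    total_width(intersection_footprint(spans[i], known_span))
  }, 0)
  frac <- inside_bp / (rec$end - rec$start)
  rec$location <- ifelse(exonic_hit, "excluded",
                         ifelse(frac > 0.5, "intronic", "intergenic"))
  rec
}

#' Coding-potential filter
#'
#' Scores each transcript (spliced exon sequence) and keeps non-coding
#' candidates (CP < cutoff; the boundary itself is coding).
#'
#' @param rec candidate records.
#' @param ts the `transcript_set` the records came from.
#' @param genome named `DNAStringSet`.
#' @param model a `cp_model`.
#' @param coding_cutoff inclusive coding boundary (default 0.364).
#' @return filtered records with `cp_score` filled in.
#' @export
stage_coding_potential <- function(rec, ts, genome, model,
                                   coding_cutoff = 0.364) {
  rec$cp_score <- vapply(rec$id, function(id)
    coding_potential(transcript_sequence(ts, id, genome), model), 0)
  rec[!is_coding(rec$cp_score, coding_cutoff), , drop = FALSE]
}

#' Spliced transcript sequence in sense orientation
#' @param ts `transcript_set`.
#' @param id transcript id.
#' @param genome named `DNAStringSet`.
#' @return character sequence.
#' @export
transcript_sequence <- function(ts, id, genome) {
  e <- GenomicRanges::sort(ts$exons[[id]])
  chrom <- as.character(GenomicRanges::seqnames(e)[1L])
  parts <- vapply(seq_along(e), function(i)
    as.character(Biostrings::subseq(genome[[chrom]],
                                    GenomicRanges::start(e)[i],
                                    GenomicRanges::end(e)[i])), "")
  s <- paste(parts, collapse = "")
  if (as.character(GenomicRanges::strand(e)[1L]) == "-") revcomp_chr(s)
  else s
}

#' Chromatin-signature filter (H3K36me3 body end + H3K4me3 promoter)
#'
#' Keeps transcripts whose 200 bp strand-aware upstream flank of the 3'
#' terminus overlaps H3K36me3 and whose 1 kb upstream-of-TSS proximal
#' promoter region overlaps H3K4me3. The downstream 200 bp flank serves as
#' the control side of the reported Jaccard pair.
#'
#' @param rec candidate records.
#' @param h3k36me3,h3k4me3 `GRanges` peak sets.
#' @param tts_flank,ppr_len flank sizes in bp (defaults 200 and 1000).
#' @return list: `records` (filtered), `jaccard_up`, `jaccard_down`
#'   (H3K36me3 Jaccard of the up- and downstream TTS flanks).
#' @export
stage_h3k36me3_h3k4me3 <- function(rec, h3k36me3, h3k4me3,
                                   tts_flank = 200, ppr_len = 1000) {
  if (nrow(rec) == 0L)
    return(list(records = rec, jaccard_up = NA_real_,
                jaccard_down = NA_real_))
  flanks <- function(side, anchor, len) {
    suppressWarnings(do.call(c, lapply(seq_len(nrow(rec)), function(i)
      flank_interval(rec$chrom[i], pos = rec[[anchor]][i], length = len,
                     side = side, strand = rec$strand[i]))))
  }
  up_tts <- flanks("upstream", "tts", tts_flank)
  down_tts <- flanks("downstream", "tts", tts_flank)
  ppr <- flanks("upstream", "tss", ppr_len)
  k36 <- normalize_intervals(h3k36me3)
  keep <- IRanges::overlapsAny(up_tts, k36, ignore.strand = TRUE) &
    IRanges::overlapsAny(ppr, normalize_intervals(h3k4me3),
                         ignore.strand = TRUE)
  jac <- function(x) tryCatch(jaccard_index(x, k36), error = function(e) 0)
  list(records = rec[keep, , drop = FALSE],
       jaccard_up = jac(up_tts), jaccard_down = jac(down_tts))
}

#' Enhancer-overlap filter
#'
#' Keeps transcripts whose span overlaps an enhancer state call; records
#' the fraction of the best-overlapped enhancer covered by the transcript.
#'
#' @param rec candidate records.
#' @param enhancers enhancer state calls (data.frame from
#'   [classify_enhancers()]) or a `GRanges`.
#' @return filtered records with an `enhancer_cover` column.
#' @export
stage_enhancer_overlap <- function(rec, enhancers) {
  enh <- if (is.data.frame(enhancers)) states_to_granges(enhancers)
  else enhancers
  if (nrow(rec) == 0L) { rec$enhancer_cover <- numeric(0); return(rec) }
  spans <- intervals(rec$chrom, rec$start, rec$end)
  hits <- GenomicRanges::findOverlaps(spans, enh, ignore.strand = TRUE)
  rec$enhancer_cover <- 0
  if (length(hits)) {
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      spans[S4Vectors::queryHits(hits)], enh[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE)) /
      GenomicRanges::width(enh[S4Vectors::subjectHits(hits)])
    agg <- tapply(ov, S4Vectors::queryHits(hits), max)
    rec$enhancer_cover[as.integer(names(agg))] <- agg
  }
  rec[rec$enhancer_cover > 0, , drop = FALSE]
}

#' CAGE and polyadenylation filter
#'
#' Keeps transcripts with a qualifying CAGE cluster (IDR score >=
#' `idr_min`) whose representative peak falls inside the 1 kb proximal
#' promoter region, and that are polyadenylated. The representative peak
#' is the highest-IDR cluster, ties broken by proximity to the TSS.
#'
#' @param rec candidate records.
#' @param cage `GRanges` from [read_cage()].
#' @param idr_min minimum IDR score (default 0.77).
#' @param ppr_len promoter length upstream of the TSS (default 1000).
#' @return filtered records with `cage_peak` filled in.
#' @export
stage_cage_polya <- function(rec, cage, idr_min = 0.77, ppr_len = 1000) {
  if (nrow(rec) == 0L) return(rec)
  cage <- cage[S4Vectors::mcols(cage)$idr_score >= idr_min]
  peaks <- S4Vectors::mcols(cage)$peak_pos
  cchr <- as.character(GenomicRanges::seqnames(cage))
  keep <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    ppr <- flank_interval(rec$chrom[i], pos = rec$tss[i], length = ppr_len,
                          side = "upstream", strand = rec$strand[i])
    inside <- cchr == rec$chrom[i] & peaks >= iv_start(ppr) &
      peaks < iv_end(ppr)
    if (!any(inside)) next
    cand <- which(inside)
    best <- cand[order(-S4Vectors::mcols(cage)$idr_score[cand],
                       abs(peaks[cand] - rec$tss[i]))][1L]
    rec$cage_peak[i] <- peaks[best]
    keep[i] <- TRUE
  }
  rec <- rec[keep, , drop = FALSE]
  rec[rec$polyadenylated, , drop = FALSE]
}

#' TFBS-intersection filter
#'
#' Keeps transcripts whose span intersects at least one TFBS peak of a TF
#' with count data, attaching the intersected TFBS ids and TF names.
#'
#' @param rec candidate records.
#' @param tf_peaks `GRanges` with metadata columns `name` (TFBS id) and
#'   `tf` (factor name).
#' @return filtered records with list-columns `tfbs_ids` and `tfs`.
#' @export
stage_tfbs <- function(rec, tf_peaks) {
  if (nrow(rec) == 0L) {
    rec$tfbs_ids <- list(); rec$tfs <- list(); return(rec)
  }
  spans <- intervals(rec$chrom, rec$start, rec$end)
  hits <- GenomicRanges::findOverlaps(spans, tf_peaks,
                                      ignore.strand = TRUE)
  ids <- S4Vectors::mcols(tf_peaks)$name
  tfs <- S4Vectors::mcols(tf_peaks)$tf
  rec$tfbs_ids <- lapply(seq_len(nrow(rec)), function(i)
    ids[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]])
  rec$tfs <- lapply(seq_len(nrow(rec)), function(i)
    unique(tfs[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]]))
  rec[lengths(rec$tfbs_ids) > 0L, , drop = FALSE]
}

#' Final occlusion call and cascade report
#'
#' A transcript is an EOTr iff it survived every stage and at least one of
#' its intersected TFBSs belongs to a TF whose fitted binding parameter is
#' unfavorable (gamma < 1).
#'
#' @param rec records surviving [stage_tfbs()].
#' @param affinity_calls data.frame with columns `tfbs_id` (or `tf`) and
#'   `call` ("favorable"/"unfavorable").
#' @return records with `is_eotr` set.
#' @export
finalize_eotrs <- function(rec, affinity_calls) {
  if (nrow(rec) == 0L) return(rec)
  key <- if ("tfbs_id" %in% names(affinity_calls)) "tfbs_id" else "tf"
  calls <- setNames(as.character(affinity_calls$call),
                    as.character(affinity_calls[[key]]))
  pick <- if (key == "tfbs_id") rec$tfbs_ids else rec$tfs
  rec$is_eotr <- vapply(pick, function(k)
    any(calls[as.character(k)] == "unfavorable", na.rm = TRUE), TRUE)
  rec
}

#' Run the full filtering cascade
#'
#' @param ts candidate `transcript_set`.
#' @param known_genes annotated `transcript_set`.
#' @param genome named `DNAStringSet`.
#' @param cp_model trained `cp_model`.
#' @param h3k36me3,h3k4me3 `GRanges` peak sets.
#' @param enhancers enhancer state calls.
#' @param cage CAGE clusters (`GRanges`).
#' @param tf_peaks TFBS peaks (`GRanges` with `name`, `tf`).
#' @param affinity_calls per-TF or per-TFBS favorability calls.
#' @param idr_min,coding_cutoff,tts_flank,ppr_len stage parameters.
#' @return list: `records` (final), `report` (per-stage counts split by
#'   location), `jaccard_up`, `jaccard_down`.
#' @export
run_cascade <- function(ts, known_genes, genome, cp_model, h3k36me3,
                        h3k4me3, enhancers, cage, tf_peaks,
                        affinity_calls, idr_min = 0.77,
                        coding_cutoff = 0.364, tts_flank = 200,
                        ppr_len = 1000) {
  report <- list()
  note <- function(stage, rec) {
    rbind(report$counts,
          data.frame(stage = stage, total = nrow(rec),
                     intronic = sum(rec$location == "intronic"),
                     intergenic = sum(rec$location == "intergenic"),
                     stringsAsFactors = FALSE))
  }
  rec <- annotate_location(ts, known_genes)
  rec <- rec[rec$location != "excluded", , drop = FALSE]
  report$counts <- note("unknown_function", rec)
  rec <- stage_coding_potential(rec, ts, genome, cp_model, coding_cutoff)
  report$counts <- note("noncoding", rec)
  st <- stage_h3k36me3_h3k4me3(rec, h3k36me3, h3k4me3, tts_flank, ppr_len)
  rec <- st$records
  report$counts <- note("h3k36me3_h3k4me3", rec)
  rec <- stage_enhancer_overlap(rec, enhancers)
  report$counts <- note("enhancer_overlap", rec)
  rec <- stage_cage_polya(rec, cage, idr_min, ppr_len)
  report$counts <- note("cage_polya", rec)
  rec <- stage_tfbs(rec, tf_peaks)
  report$counts <- note("tfbs", rec)
  rec <- finalize_eotrs(rec, affinity_calls)
  report$counts <- note("eotr", rec[rec$is_eotr, , drop = FALSE])
  list(records = rec, report = report$counts,
       jaccard_up = st$jaccard_up, jaccard_down = st$jaccard_down)
}
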