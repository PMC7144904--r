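# Readers and writers for the plain-text formats the pipeline touches.
# All genomic text formats are tab-separated, newline-terminated; coordinates
# are converted to the internal 0-based half-open convention on read.

read_tab_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines[nzchar(lines) & !startsWith(lines, "#") &
          !startsWith(lines, "track") & !startsWith(lines, "browser")]
}

parse_error <- function(path, i, msg) {
  stop(sprintf("%s: line %d: %s", basename(path), i, msg), call. = FALSE)
}

#' Read / write BED intervals
#'
#' Accepts BED3-BED6 and broadPeak/narrowPeak (columns beyond 6 are kept in
#' `extra`). Scores and names are preserved round-trip.
#'
#' @param path file path.
#' @return `read_bed`: a `GRanges` with optional `name`, `score`, `extra`
#'   metadata columns.
#' @export
read_bed <- function(path) {
  lines <- read_tab_lines(path)
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    parse_error(path, which(nf < 3L)[1L], "fewer than 3 BED columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (any(is.na(start) | is.na(end)))
    parse_error(path, which(is.na(start) | is.na(end))[1L],
                "non-numeric coordinate")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    parse_error(path, bad[1L],
                sprintf("invalid interval %s:%s-%s", chrom[bad[1L]],
                        start[bad[1L]], end[bad[1L]]))
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[4] %||% ".", ""), ".")
  score <- ifelse(nf >= 5L,
                  suppressWarnings(as.numeric(
                    vapply(fields, function(f) f[5] %||% "0", ""))), 0)
  score[is.na(score)] <- 0
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[6] %||% ".", ""),
                   ".")
  strand[!strand %in% c("+", "-")] <- "."
  gr <- intervals(chrom, start, end, strand = strand, name = name,
                  score = score)
  if (any(nf > 6L)) {
    S4Vectors::mcols(gr)$extra <- vapply(
      fields, function(f) paste(f[-seq_len(6L)], collapse = "\t"), "")
  }
  gr
}

#' @rdname read_bed
#' @param x `GRanges` to write.
#' @export
write_bed <- function(x, path) {
  if (length(x) == 0L) { writeLines(character(), path); return(invisible(path)) }
  mc <- S4Vectors::mcols(x)
  name <- if ("name" %in% names(mc)) mc$name else "."
  score <- if ("score" %in% names(mc)) mc$score else 0
  strand <- as.character(GenomicRanges::strand(x))
  strand[strand == "*"] <- "."
  out <- paste(as.character(GenomicRanges::seqnames(x)),
               format(iv_start(x), scientific = FALSE, trim = TRUE),
               format(iv_end(x), scientific = FALSE, trim = TRUE),
               name, score, strand, sep = "\t")
  if ("extra" %in% names(mc)) out <- paste(out, mc$extra, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
  out <- rep(NA_character_, length(attrs))
  ok <- lengths(regmatches(attrs, gregexpr(paste0(key, ' "'), attrs))) > 0
  out[ok] <- sub('"$', "", sub(paste0(key, ' "'), "", m))
  out
}

#' Read transcript models from a GTF file
#'
#' Parses `exon` features (GENCODE dialect; 1-based inclusive coordinates,
#' converted to 0-based half-open). TSS/TTS are strand-aware: the TSS is the
#' leftmost base for `+` transcripts and the rightmost for `-`. Optional
#' transcript-level attributes `polyadenylated` ("true"/"false") and `cpm`
#' are honoured when present.
#'
#' @param path GTF file path.
#' @return a `transcript_set`: list with `tx` (data.frame: id, chrom, strand,
#'   start, end, tss, tts, spliced, polyadenylated, cpm) and `exons`
#'   (named `GRangesList`).
#' @export
read_gtf_transcripts <- function(path) {
  lines <- read_tab_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    parse_error(path, which(nf < 9L)[1L], "fewer than 9 GTF columns")
  feat <- vapply(fields, `[`, "", 3L)
  keep <- which(feat == "exon")
  if (length(keep) == 0L) stop("no exon features in ", path)
  f <- fields[keep]
  chrom <- vapply(f, `[`, "", 1L)
  start1 <- as.numeric(vapply(f, `[`, "", 4L))
  end1 <- as.numeric(vapply(f, `[`, "", 5L))
  strand <- vapply(f, `[`, "", 7L)
  attrs <- vapply(f, `[`, "", 9L)
  txid <- gtf_attr(attrs, "transcript_id")
  if (anyNA(txid))
    parse_error(path, keep[which(is.na(txid))[1L]],
                "exon without transcript_id")
  if (any(start1 > end1))
    parse_error(path, keep[which(start1 > end1)[1L]], "start > end")
  polya <- gtf_attr(attrs, "polyadenylated")
  cpm <- suppressWarnings(as.numeric(gtf_attr(attrs, "cpm")))
  ex <- intervals(chrom, start1 - 1, end1, strand = strand)
  S4Vectors::mcols(ex)$transcript_id <- txid
  transcript_set_from_exons(ex, polya = polya, cpm = cpm)
}

transcript_set_from_exons <- function(ex, polya = NULL, cpm = NULL) {
  txid <- S4Vectors::mcols(ex)$transcript_id
  ids <- unique(txid)
  exl <- GenomicRanges::split(GenomicRanges::granges(ex), factor(txid, ids))
  tx <- do.call(rbind, lapply(ids, function(id) {
    e <- exl[[id]]
    if (length(unique(as.character(GenomicRanges::seqnames(e)))) > 1L ||
        length(unique(as.character(GenomicRanges::strand(e)))) > 1L)
      stop("transcript ", id, ": exons on multiple chroms/strands")
    e <- GenomicRanges::sort(e)
    if (length(e) > 1L &&
        any(GenomicRanges::start(e)[-1L] <=
              GenomicRanges::end(e)[-length(e)]))
      stop("transcript ", id, ": overlapping exons")
    st <- as.character(GenomicRanges::strand(e)[1L])
    s <- min(GenomicRanges::start(e)) - 1; en <- max(GenomicRanges::end(e))
    data.frame(id = id,
               chrom = as.character(GenomicRanges::seqnames(e)[1L]),
               strand = st, start = s, end = en,
               tss = if (st == "-") en else s,
               tts = if (st == "-") s else en,
               spliced = length(e) > 1L,
               stringsAsFactors = FALSE)
  }))
  first <- match(ids, txid)
  tx$polyadenylated <- if (!is.null(polya))
    tolower(polya[first]) %in% "true" else FALSE
  tx$cpm <- if (!is.null(cpm)) ifelse(is.na(cpm[first]), 0, cpm[first]) else 0
  if (any(tx$cpm < 0)) stop("cpm must be >= 0")
  structure(list(tx = tx, exons = exl), class = "transcript_set")
}

#' Transcript spans as an interval set
#' @param ts a `transcript_set`.
#' @return `GRanges` named by transcript id.
#' @export
transcript_spans <- function(ts) {
  intervals(ts$tx$chrom, ts$tx$start, ts$tx$end, strand = ts$tx$strand,
            name = ts$tx$id)
}

#' Write transcript models to GTF
#' @param ts a `transcript_set`.
#' @param path output path.
#' @export
write_gtf_transcripts <- function(ts, path) {
  rows <- unlist(lapply(seq_len(nrow(ts$tx)), function(i) {
    t <- ts$tx[i, ]
    e <- ts$exons[[t$id]]
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; polyadenylated "%s"; cpm "%g";',
      t$id, t$id, tolower(t$polyadenylated), t$cpm)
    paste(t$chrom, "eotrscan", "exon", GenomicRanges::start(e),
          GenomicRanges::end(e), ".", t$strand, ".", attrs, sep = "\t")
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Read / write a bedGraph coverage track
#'
#' @param path bedGraph path (0-based half-open, 4th column value).
#' @return `read_bedgraph`: a coverage track (`RleList`, one run-length
#'   vector per chromosome; uncovered bases are 0).
#' @export
read_bedgraph <- function(path) {
  lines <- read_tab_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    parse_error(path, which(lengths(fields) < 4L)[1L],
                "fewer than 4 bedGraph columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- as.numeric(vapply(fields, `[`, "", 2L))
  end <- as.numeric(vapply(fields, `[`, "", 3L))
  value <- as.numeric(vapply(fields, `[`, "", 4L))
  if (any(!is.finite(value)))
    parse_error(path, which(!is.finite(value))[1L], "non-finite value")
  if (any(start >= end))
    parse_error(path, which(start >= end)[1L], "start >= end")
  gr <- intervals(chrom, start, end, score = value)
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1L))
    stop("bedGraph runs overlap in ", basename(path))
  coverage_from_runs(gr)
}

coverage_from_runs <- function(gr) {
  GenomicRanges::coverage(gr, weight = S4Vectors::mcols(gr)$score)
}

#' @rdname read_bedgraph
#' @param track an `RleList` coverage track.
#' @export
write_bedgraph <- function(track, path) {
  out <- unlist(lapply(names(track), function(chr) {
    r <- track[[chr]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0, ends[-length(ends)])
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (!any(keep)) return(character())
    paste(chr, format(starts[keep], scientific = FALSE, trim = TRUE),
          format(ends[keep], scientific = FALSE, trim = TRUE),
          format(vals[keep], scientific = FALSE, trim = TRUE), sep = "\t")
  }))
  writeLines(out, path)
  invisible(path)
}

#' Mean coverage of a track over an interval
#'
#' Bases outside the covered span count as 0.
#' @param track `RleList` coverage track.
#' @param chrom,start,end 0-based half-open query interval.
#' @return numeric mean.
#' @export
coverage_mean <- function(track, chrom, start, end) {
  if (start >= end) stop("start >= end")
  if (!chrom %in% names(track)) return(0)
  r <- track[[chrom]]
  n <- length(r)
  lo <- max(0, start); hi <- min(n, end)
  s <- if (hi > lo) sum(as.numeric(S4Vectors::runValue(
    IRanges::Views(r, lo + 1, hi)[[1]])) *
      S4Vectors::runLength(IRanges::Views(r, lo + 1, hi)[[1]])) else 0
  s / (end - start)
}

#' Read / write BEDPE chromatin interactions
#'
#' @param path BEDPE path (anchorA chrom/start/end, anchorB chrom/start/end,
#'   name, score).
#' @return `read_bedpe`: data.frame with `chromA,startA,endA,chromB,startB,
#'   endB,name,score`.
#' @export
read_bedpe <- function(path) {
  lines <- read_tab_lines(path)
  if (length(lines) == 0L)
    return(data.frame(chromA = character(), startA = numeric(),
                      endA = numeric(), chromB = character(),
                      startB = numeric(), endB = numeric(),
                      name = character(), score = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6L))
    parse_error(path, which(lengths(fields) < 6L)[1L],
                "fewer than 6 BEDPE columns")
  g <- function(i, def = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[i] else def, "")
  d <- data.frame(chromA = g(1), startA = as.numeric(g(2)),
                  endA = as.numeric(g(3)), chromB = g(4),
                  startB = as.numeric(g(5)), endB = as.numeric(g(6)),
                  name = g(7, "."), score = suppressWarnings(
                    as.numeric(g(8, "1"))), stringsAsFactors = FALSE)
  d$score[is.na(d$score)] <- 1
  if (any(d$startA >= d$endA | d$startB >= d$endB))
    parse_error(path, which(d$startA >= d$endA | d$startB >= d$endB)[1L],
                "anchor start >= end")
  d
}

#' @rdname read_bedpe
#' @param loops data.frame as returned by `read_bedpe`.
#' @export
write_bedpe <- function(loops, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  writeLines(paste(loops$chromA, fmt(loops$startA), fmt(loops$endA),
                   loops$chromB, fmt(loops$startB), fmt(loops$endB),
                   loops$name %||% ".", loops$score %||% 1, sep = "\t"),
             path)
  invisible(path)
}

#' Read a FASTA genome
#' @param path FASTA path.
#' @return named `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Read / write a TSV count matrix
#'
#' First column = feature id, remaining columns = integer counts per sample.
#' An optional comment line `#library_sizes: s1=...,s2=...` carries total
#' mapped reads; otherwise column sums are used.
#'
#' @param path TSV path.
#' @return list with `counts` (integer matrix) and `library_sizes`.
#' @export
read_count_matrix <- function(path) {
  raw <- readLines(path)
  libline <- grep("^#library_sizes:", raw, value = TRUE)
  tab <- read.table(text = raw[!startsWith(raw, "#")], header = TRUE,
                    sep = "\t", check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  if (any(counts < 0)) stop("negative counts in ", path)
  lib <- colSums(counts)
  if (length(libline)) {
    kv <- strsplit(strsplit(sub("^#library_sizes:\\s*", "", libline[1]),
                            ",")[[1]], "=")
    lib2 <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                     vapply(kv, `[`, "", 1L))
    lib[names(lib2)] <- lib2
  }
  list(counts = counts, library_sizes = lib)
}

#' @rdname read_count_matrix
#' @param counts integer matrix (features x samples).
#' @param library_sizes optional named numeric vector.
#' @export
write_count_matrix <- function(counts, path, library_sizes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(library_sizes))
    writeLines(paste0("#library_sizes: ",
                      paste(names(library_sizes), library_sizes, sep = "=",
                            collapse = ",")), con)
  writeLines(paste(c("feature", colnames(counts)), collapse = "\t"), con)
  writeLines(paste(rownames(counts),
                   apply(counts, 1, paste, collapse = "\t"), sep = "\t"),
             con)
  invisible(path)
}

#' Read CAGE clusters
#'
#' BED6+1: name column holds the cluster id, score the IDR reproducibility
#' score in [0, 1], and an optional 7th column the 0-based representative
#' peak position (defaults to the interval midpoint). Peak positions outside
#' the cluster are rejected.
#'
#' @param path CAGE BED path.
#' @return `GRanges` with `name`, `idr_score`, `peak_pos` metadata.
#' @export
read_cage <- function(path) {
  gr <- read_bed(path)
  if (length(gr) == 0L) return(gr)
  mc <- S4Vectors::mcols(gr)
  idr <- mc$score
  if (any(idr < 0 | idr > 1)) stop("CAGE idr_score outside [0,1]")
  peak <- if ("extra" %in% names(mc))
    suppressWarnings(as.numeric(mc$extra)) else rep(NA_real_, length(gr))
  mid <- floor((iv_start(gr) + iv_end(gr)) / 2)
  peak[is.na(peak)] <- mid[is.na(peak)]
  if (any(peak < iv_start(gr) | peak >= iv_end(gr)))
    stop("CAGE peak_pos outside its cluster")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = mc$name,
                                               idr_score = idr,
                                               peak_pos = peak)
  gr
}
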