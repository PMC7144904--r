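# Per-base brute-force oracles on a toy chromosome, independent of the
# interval algebra they check: every set is expanded to a logical mask.

TOY_LEN <- 10000L

mask_of <- function(gr, len = TOY_LEN) {
  m <- logical(len)
  for (i in seq_along(gr)) {
    s <- eotrscan::iv_start(gr)[i]; e <- eotrscan::iv_end(gr)[i]
    m[(s + 1):e] <- TRUE
  }
  m
}

mask_to_intervals <- function(m, chrom = "toy") {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values
  if (!any(keep)) return(GenomicRanges::GRanges())
  eotrscan::intervals(chrom, starts[keep], ends[keep])
}

random_set <- function(n, len = TOY_LEN, max_w = 400L, chrom = "toy") {
  s <- sample.int(len - max_w, n)
  w <- sample.int(max_w, n)
  eotrscan::intervals(chrom, s, pmin(len, s + w))
}

same_footprint <- function(a, b) {
  identical(mask_of(a), mask_of(b))
}

# exact AUROC by rank statistic
auroc <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_along(scores_pos)]) -
      length(scores_pos) * (length(scores_pos) + 1) / 2) /
    (length(scores_pos) * length(scores_neg))
}

# small shared simulation (and one pipeline run on it), built once per
# test run
sim_small_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "eotrscan_sim_small")
      cfg <- eotrscan::sim_config(seed = 7, n_eotr = 24, n_erna = 24,
                                  n_inert = 10, n_mrna_like = 12,
                                  n_intron_fragment = 12)
      eotrscan::simulate_loci(cfg, dir)
    }
    dir
  }
})

sim_small_pipeline <- local({
  res <- NULL
  function() {
    if (is.null(res))
      res <<- eotrscan::run_pipeline(
        sim_small_dir(),
        out_dir = file.path(tempdir(), "eotrscan_sim_small_reports"),
        seed = 11)
    res
  }
})
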