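mk_ts <- function(df, exons = NULL) {
  # df: id, chrom, strand, start, end (single-exon transcripts unless
  # exons supplies a list of start/end matrices)
  grl <- lapply(seq_len(nrow(df)), function(i) {
    ex <- if (is.null(exons) || is.null(exons[[df$id[i]]]))
      cbind(df$start[i], df$end[i]) else exons[[df$id[i]]]
    gr <- intervals(df$chrom[i], ex[, 1], ex[, 2], strand = df$strand[i])
    S4Vectors::mcols(gr)$transcript_id <- df$id[i]
    gr
  })
  all <- suppressWarnings(do.call(c, grl))
  ts <- eotrscan:::transcript_set_from_exons(all)
  if ("polya" %in% names(df))
    ts$tx$polyadenylated <- df$polya[match(ts$tx$id, df$id)]
  ts
}

test_that("annotate_location: exon overlap excludes, majority rules", {
  genes <- mk_ts(data.frame(id = "g1", chrom = "toy", strand = "+",
                            start = 1000, end = 4000),
                 exons = list(g1 = rbind(c(1000, 2000), c(3000, 4000))))
  cand <- mk_ts(data.frame(
    id = c("in_intron", "on_exon", "straddle"), chrom = "toy",
    strand = "+", start = c(2100, 1500, 2100), end = c(2900, 2500, 6100)),
    exons = list(straddle = rbind(c(2100, 2900), c(4100, 6100))))
  rec <- annotate_location(cand, genes)
  expect_equal(rec$location[rec$id == "in_intron"], "intronic")
  expect_equal(rec$location[rec$id == "on_exon"], "excluded")
  # straddle: spliced over the terminal exon; 1900 of 4000 span bp inside
  # the gene body -> majority intergenic
  expect_equal(rec$location[rec$id == "straddle"], "intergenic")
})

test_that("longest ORF and Fickett behave on edge cases", {
  o <- longest_orf("TTTATGAAACCCGGGTAATTT")
  expect_equal(o$length, 15)  # ATG AAA CCC GGG TAA
  expect_equal(substr(o$orf, 1, 3), "ATG")
  expect_equal(longest_orf("CCCCCCCCCCCC")$length, 0)
  withr::local_seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_gte(fickett_score(s), 0)
})

test_that("coding potential separates planted coding from noncoding", {
  withr::local_seed(31)
  codons <- eotrscan:::.codons()
  mk_coding <- function() paste0(
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
    "ATG", paste(sample(codons, 120, TRUE), collapse = ""), "TAA",
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""))
  mk_noncoding <- function()
    paste(sample(c("A", "C", "G", "T"), 420, TRUE), collapse = "")
  train_c <- replicate(30, mk_coding())
  train_n <- replicate(30, mk_noncoding())
  model <- train_cp(train_c, train_n)
  test_c <- replicate(25, mk_coding())
  test_n <- replicate(25, mk_noncoding())
  cp_c <- vapply(test_c, coding_potential, 0, model = model)
  cp_n <- vapply(test_n, coding_potential, 0, model = model)
  expect_true(all(cp_c >= 0 & cp_c <= 1))
  expect_gte(auroc(cp_c, cp_n), 0.95)
  # boundary is inclusive on the coding side
  expect_true(is_coding(0.364))
  expect_false(is_coding(0.3639))
  expect_error(coding_potential(paste(rep("A", 50), collapse = ""),
                                model), "60 nt")
})

test_that("chromatin-signature stage keeps EOTr geometry, drops others", {
  rec <- eotrscan:::new_records(mk_ts(data.frame(
    id = c("good", "no_ppr"), chrom = "toy", strand = "+",
    start = c(1000, 5000), end = c(3000, 7000))))
  rec$location <- "intergenic"
  h3k36 <- iv <- intervals("toy", c(1200, 5200), c(3050, 7050))
  h3k4me3 <- intervals("toy", 100, 1100)  # covers only good's PPR
  st <- stage_h3k36me3_h3k4me3(rec, h3k36, h3k4me3)
  expect_equal(st$records$id, "good")
  expect_gt(st$jaccard_up, st$jaccard_down)
})

test_that("CAGE/polyA stage: PPR containment, IDR cutoff, polyA", {
  base <- mk_ts(data.frame(id = c("t1", "t2", "t3"), chrom = "toy",
                           strand = "+", start = c(2000, 2000, 2000),
                           end = c(4000, 4000, 4000),
                           polya = c(TRUE, FALSE, TRUE)))
  rec <- eotrscan:::new_records(base)
  rec$location <- "intergenic"
  cage_line <- function(s, e, idr, peak)
    sprintf("toy\t%d\t%d\tc\t%s\t+\t%d", s, e, idr, peak)
  p <- withr::local_tempfile(lines = c(cage_line(1500, 1600, "0.9", 1550)))
  cage <- read_cage(p)
  out <- stage_cage_polya(rec, cage)
  expect_equal(out$id, c("t1", "t3"))   # t2 fails polyA
  expect_equal(out$cage_peak, c(1550, 1550))
  # peak 1.5 kb upstream of the TSS is outside the 1 kb PPR
  p2 <- withr::local_tempfile(lines = cage_line(400, 600, "0.9", 500))
  expect_equal(nrow(stage_cage_polya(rec, read_cage(p2))), 0L)
  # IDR below threshold
  p3 <- withr::local_tempfile(lines = cage_line(1500, 1600, "0.5", 1550))
  expect_equal(nrow(stage_cage_polya(rec, read_cage(p3))), 0L)
})

test_that("TFBS stage attaches intersected sites; finalize needs an
          unfavorable call", {
  base <- mk_ts(data.frame(id = c("hit", "miss"), chrom = "toy",
                           strand = "+", start = c(1000, 8000),
                           end = c(3000, 9000)))
  rec <- eotrscan:::new_records(base)
  rec$location <- "intergenic"
  tfbs <- intervals("toy", c(1500, 2500), c(1600, 2600),
                    name = c("s1", "s2"), score = 0)
  S4Vectors::mcols(tfbs)$tf <- c("TFA", "TFB")
  out <- stage_tfbs(rec, tfbs)
  expect_equal(out$id, "hit")
  expect_setequal(out$tfbs_ids[[1]], c("s1", "s2"))
  fav <- finalize_eotrs(out, data.frame(tf = c("TFA", "TFB"),
                                        call = "favorable"))
  expect_false(any(fav$is_eotr))
  mix <- finalize_eotrs(out, data.frame(tf = c("TFA", "TFB"),
                                        call = c("favorable",
                                                 "unfavorable")))
  expect_true(all(mix$is_eotr))
})

test_that("truth_join computes confusion counts and flags unknown ids", {
  truth <- data.frame(id = paste0("t", 1:60),
                      label = rep(c("eotr", "other"), c(20, 40)))
  perfect <- truth; names(perfect) <- c("id", "label")
  r <- truth_join(perfect, truth)
  expect_equal(r$precision[r$label == "eotr"], 1)
  expect_equal(r$recall[r$label == "eotr"], 1)
  none <- data.frame(id = truth$id, label = "other")
  r2 <- truth_join(none, truth)
  expect_equal(r2$recall[r2$label == "eotr"], 0)
  one_swap <- truth
  one_swap$label[1] <- "other"
  r3 <- truth_join(one_swap, truth)
  expect_equal(r3$recall[r3$label == "eotr"], 19 / 20)
  expect_error(truth_join(data.frame(id = "zz", label = "x"), truth),
               "unmatched")
})
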