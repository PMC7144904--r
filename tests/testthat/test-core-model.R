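test_that("BED round-trip preserves coordinates, names, scores, strand", {
  withr::local_seed(11)
  gr <- intervals(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                  start = s <- sample.int(1e6, 100),
                  end = s + sample.int(5000, 100),
                  strand = sample(c("+", "-", "."), 100, TRUE),
                  name = paste0("iv", 1:100),
                  score = round(runif(100), 3))
  path <- withr::local_tempfile()
  write_bed(gr, path)
  back <- read_bed(path)
  expect_equal(iv_start(back), iv_start(gr))
  expect_equal(iv_end(back), iv_end(gr))
  expect_equal(S4Vectors::mcols(back)$name, S4Vectors::mcols(gr)$name)
  expect_equal(S4Vectors::mcols(back)$score, S4Vectors::mcols(gr)$score)
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(gr)))
})

test_that("readers reject malformed records with the offending line", {
  p <- withr::local_tempfile(lines = c("chr1\t0\t10\tA\t0\t+",
                                       "chr1\t10\t5"))
  expect_error(read_bed(p), "line 2")
  p2 <- withr::local_tempfile(lines = "chr1\t0")
  expect_error(read_bed(p2), "line 1")
  p3 <- withr::local_tempfile(lines = "chr1\tx\t10")
  expect_error(read_bed(p3), "line 1")
  expect_error(intervals("chr1", 10, 5), "start")
  expect_error(intervals("", 0, 5), "chrom")
  bg <- withr::local_tempfile(lines = c("chr1\t0\t10\t1",
                                        "chr1\t5\t15\t2"))
  expect_error(read_bedgraph(bg), "overlap")
})

test_that("GTF transcripts convert coordinates and are strand-aware", {
  p <- withr::local_tempfile(lines = c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\ttranscript_id "t1";',
    'chr1\tx\texon\t501\t600\t.\t-\t.\ttranscript_id "t2"; cpm "4";',
    'chr1\tx\texon\t801\t900\t.\t-\t.\ttranscript_id "t2";'))
  ts <- read_gtf_transcripts(p)
  t1 <- ts$tx[ts$tx$id == "t1", ]
  expect_equal(t1$start, 100); expect_equal(t1$end, 200)
  expect_equal(t1$tss, 100); expect_equal(t1$tts, 200)
  expect_false(t1$spliced)
  t2 <- ts$tx[ts$tx$id == "t2", ]
  expect_equal(t2$tss, 900)   # rightmost end on the minus strand
  expect_equal(t2$tts, 500)
  expect_true(t2$spliced)
  expect_equal(t2$cpm, 4)

  noid <- withr::local_tempfile(lines =
    "chr1\tx\texon\t1\t10\t.\t+\t.\tgene_id \"g\";")
  expect_error(read_gtf_transcripts(noid), "transcript_id")
  ovl <- withr::local_tempfile(lines = c(
    'chr1\tx\texon\t1\t100\t.\t+\t.\ttranscript_id "t";',
    'chr1\tx\texon\t50\t150\t.\t+\t.\ttranscript_id "t";'))
  expect_error(read_gtf_transcripts(ovl), "overlapping")
})

test_that("flank is strand-mirrored and clips at the chromosome start", {
  up <- flank_interval("chr1", pos = 1000, length = 1000,
                       side = "upstream", strand = "+")
  expect_equal(c(iv_start(up), iv_end(up)), c(0, 1000))
  upm <- flank_interval("chr1", pos = 1000, length = 1000,
                        side = "upstream", strand = "-")
  expect_equal(c(iv_start(upm), iv_end(upm)), c(1000, 2000))
  clip <- flank_interval("chr1", pos = 300, length = 1000,
                         side = "upstream", strand = "+")
  expect_equal(c(iv_start(clip), iv_end(clip)), c(0, 300))
  dn <- flank_interval("chr1", pos = 1000, length = 200,
                       side = "downstream", strand = "-")
  expect_equal(c(iv_start(dn), iv_end(dn)), c(800, 1000))
  expect_error(flank_interval("chr1", pos = 10, length = 0,
                              side = "upstream"), "length")
})

test_that("intersect_sets honours overlap fractions and reciprocity", {
  a <- intervals("toy", 0, 10)
  b <- intervals("toy", 5, 15)
  expect_length(intersect_sets(a, b, min_frac = 0.5), 1L)
  expect_length(intersect_sets(a, b, min_frac = 0.8), 0L)
  expect_length(intersect_sets(a, intervals("toy", 50, 60)), 0L)
  expect_error(intersect_sets(a, b, min_frac = 1.5), "min_frac")
  # reciprocal: 80% of a covered but not 80% of the larger b
  a2 <- intervals("toy", 0, 10)
  b2 <- intervals("toy", 1, 100)
  expect_length(intersect_sets(a2, b2, min_frac = 0.8), 1L)
  expect_length(intersect_sets(a2, b2, min_frac = 0.8,
                               reciprocal = TRUE), 0L)
  # abutting intervals do not overlap (half-open semantics)
  expect_length(intersect_sets(intervals("toy", 0, 10),
                               intervals("toy", 10, 20)), 0L)
})

test_that("interval algebra agrees with the per-base mask oracle", {
  withr::local_seed(5)
  for (i in 1:60) {
    a <- random_set(sample(3:25, 1))
    b <- random_set(sample(3:25, 1))
    expect_true(same_footprint(merge_sets(a),
                               mask_to_intervals(mask_of(a))))
    expect_true(same_footprint(subtract_sets(a, b),
                               mask_to_intervals(mask_of(a) & !mask_of(b))))
    expect_true(same_footprint(intersection_footprint(a, b),
                               mask_to_intervals(mask_of(a) & mask_of(b))))
  }
})

test_that("coverage_mean is exact on uniform tracks and 0 off-track", {
  gr <- intervals("chr1", 100, 600, score = 3.5)
  tr <- eotrscan:::coverage_from_runs(gr)
  expect_identical(coverage_mean(tr, "chr1", 150, 450), 3.5)
  expect_identical(coverage_mean(tr, "chr1", 100, 600), 3.5)
  expect_equal(coverage_mean(tr, "chr1", 0, 100), 0)
  expect_equal(coverage_mean(tr, "chrX", 0, 100), 0)
  # partial overlap mixes covered and uncovered bases
  expect_equal(coverage_mean(tr, "chr1", 0, 200), 3.5 * 100 / 200)
  expect_error(coverage_mean(tr, "chr1", 10, 10), "start")
})

test_that("bedGraph round-trip reproduces the track", {
  p <- withr::local_tempfile(lines = c("chr1\t0\t100\t2",
                                       "chr1\t200\t300\t5",
                                       "chr2\t50\t80\t1"))
  tr <- read_bedgraph(p)
  p2 <- withr::local_tempfile()
  write_bedgraph(tr, p2)
  tr2 <- read_bedgraph(p2)
  expect_equal(coverage_mean(tr2, "chr1", 0, 300),
               coverage_mean(tr, "chr1", 0, 300))
  expect_equal(coverage_mean(tr2, "chr2", 50, 80), 1)
})

test_that("count-matrix round-trip preserves counts and library sizes", {
  m <- matrix(rpois(12, 20), 4, 3,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  p <- withr::local_tempfile()
  write_count_matrix(m, p, setNames(c(2e6, 3e6, 1e6), colnames(m)))
  back <- read_count_matrix(p)
  expect_equal(back$counts, m)
  expect_equal(unname(back$library_sizes), c(2e6, 3e6, 1e6))
})
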