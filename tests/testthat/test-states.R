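iv <- function(s, e) intervals("toy", s, e)

test_that("consensus_peaks votes per base and validates min_support", {
  r1 <- iv(c(100, 500), c(200, 600))
  r2 <- iv(c(150, 800), c(250, 900))
  cons <- consensus_peaks(list(r1, r2), min_support = 2)
  expect_true(same_footprint(cons, iv(150, 200)))
  expect_error(consensus_peaks(list(r1), min_support = 2), "min_support")
  expect_error(consensus_peaks(list(), 1), "replicate")
  # chained partial overlaps against the per-base support oracle
  withr::local_seed(13)
  for (i in 1:20) {
    reps <- lapply(1:3, function(.) random_set(8, max_w = 300))
    cons <- consensus_peaks(reps, min_support = 2)
    support <- Reduce(`+`, lapply(reps, mask_of))
    expect_true(same_footprint(cons, mask_to_intervals(support >= 2)))
  }
})

test_that("enhancer classification follows the mark combinations", {
  k4me1 <- iv(1000, 3000); p300 <- iv(1500, 2500)
  ac <- iv(1600, 1700)
  active <- classify_enhancers(k4me1, p300, ac, GenomicRanges::GRanges())
  expect_equal(active$state, "enhancer_active")
  expect_equal(active$start, 1500); expect_equal(active$end, 2500)
  poised <- classify_enhancers(k4me1, p300, GenomicRanges::GRanges(),
                               GenomicRanges::GRanges())
  expect_equal(poised$state, "enhancer_poised")
  none <- classify_enhancers(GenomicRanges::GRanges(), p300, ac, ac)
  expect_equal(nrow(none), 0L)
})

test_that("promoter classification: active rule, poised dominance", {
  k4me3 <- iv(100, 600)
  all4 <- classify_promoters(k4me3, iv(100, 600), iv(100, 600),
                             iv(100, 600), GenomicRanges::GRanges())
  expect_equal(all4$state, "promoter_active")
  poised <- classify_promoters(k4me3, GenomicRanges::GRanges(),
                               GenomicRanges::GRanges(),
                               GenomicRanges::GRanges(), iv(100, 600))
  expect_equal(poised$state, "promoter_poised")
  both <- classify_promoters(k4me3, iv(100, 600), iv(100, 600),
                             iv(100, 600), iv(100, 600))
  expect_equal(both$state, "promoter_poised")  # poised wins
  alone <- classify_promoters(k4me3, GenomicRanges::GRanges(),
                              GenomicRanges::GRanges(),
                              GenomicRanges::GRanges(),
                              GenomicRanges::GRanges())
  expect_equal(nrow(alone), 0L)
})

test_that("eRNA domains require the four positive marks and no exclusions", {
  k4me1 <- iv(1000, 3000); p300 <- iv(1500, 2500)
  ac27 <- iv(1400, 2600); ac9 <- iv(1450, 2550)
  e <- identify_erna_domains(k4me1, ac27, ac9, p300,
                             GenomicRanges::GRanges(),
                             GenomicRanges::GRanges())
  expect_equal(e$state, "erna_domain")
  e2 <- identify_erna_domains(k4me1, ac27, ac9, p300,
                              iv(2000, 2100), GenomicRanges::GRanges())
  expect_equal(nrow(e2), 0L)   # H3K36me3 excludes
  # direction: equal + and - evidence gives "."
  cage <- intervals("toy", c(1600, 1800), c(1650, 1850),
                    strand = c("+", "-"), name = c("a", "b"),
                    score = c(0.9, 0.9))
  S4Vectors::mcols(cage)$idr_score <- c(0.9, 0.9)
  S4Vectors::mcols(cage)$peak_pos <- c(1620, 1820)
  e3 <- identify_erna_domains(k4me1, ac27, ac9, p300,
                              GenomicRanges::GRanges(),
                              GenomicRanges::GRanges(), cage = cage)
  expect_equal(e3$direction, ".")
})

test_that("acetylation removal poises all enhancers and kills eRNAs", {
  withr::local_seed(2)
  k4me1 <- random_set(10, max_w = 500)
  p300 <- random_set(10, max_w = 500)
  empty <- GenomicRanges::GRanges()
  enh <- classify_enhancers(k4me1, p300, empty, empty)
  if (nrow(enh)) expect_true(all(enh$state == "enhancer_poised"))
  expect_equal(nrow(identify_erna_domains(k4me1, empty, empty, p300,
                                          empty, empty)), 0L)
})

test_that("state calls are order-independent", {
  withr::local_seed(8)
  k4me1 <- random_set(12, max_w = 400); p300 <- random_set(12, max_w = 400)
  ac <- random_set(8, max_w = 300)
  a <- classify_enhancers(k4me1, p300, ac, ac)
  b <- classify_enhancers(rev(k4me1), rev(p300), rev(ac), rev(ac))
  expect_equal(a, b)
})

test_that("heterochromatin flag uses half-open overlap", {
  region <- iv(1000, 2000)
  expect_true(heterochromatin_flag(region, iv(1500, 1600)))
  expect_false(heterochromatin_flag(region, iv(3000, 4000)))
  expect_false(heterochromatin_flag(region, iv(2000, 2100)))  # abutting
})
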