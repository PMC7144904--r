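make_test_pwm <- function() eotrscan:::sim_pwm()

test_that("pwm_from_sites applies the pseudocount arithmetic", {
  p <- pwm_from_sites(rep("ACGT", 10))
  expect_equal(unname(p$matrix[1, "A"]), 10.5 / 12)
  expect_equal(rowSums(p$matrix), rep(1, 4), ignore_attr = TRUE)
  p2 <- pwm_from_sites(c(rep("ACGT", 8), rep("TCGT", 2)))
  expect_equal(unname(p2$matrix[1, "A"]), 8.5 / 12)
  expect_equal(unname(p2$matrix[1, "T"]), 2.5 / 12)
  expect_error(pwm_from_sites(rep("ACGT", 5)), ">= 10")
  expect_error(pwm_from_sites(c(rep("ACGT", 9), "ACGTA")), "length")
})

test_that("max_binding_wts spans [0, 100] and is strand-invariant", {
  # homopolymer motif: "CCC..." scores the attainable minimum on both
  # strands ("GGG..." is equally worst), so 0 is reachable
  m <- matrix(0.05, 8, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[, "A"] <- 0.85
  pwm <- pwm_from_matrix(m)
  region <- paste0("CCCCCCCC", paste(rep("A", 8), collapse = ""),
                   "CCCCCCCC")
  expect_equal(max_binding_wts(region, pwm), 100)
  expect_equal(max_binding_wts(paste(rep("C", 20), collapse = ""), pwm),
               0)
  expect_equal(max_binding_wts(eotrscan:::revcomp_chr(region), pwm),
               max_binding_wts(region, pwm))
  sim <- make_test_pwm()
  r2 <- paste0("AAAATTTT", eotrscan:::SIM_MOTIF, "AAAATTTT")
  expect_equal(max_binding_wts(r2, sim), 100)
  expect_equal(max_binding_wts(eotrscan:::revcomp_chr(r2), sim), 100)
  expect_error(max_binding_wts("ACGT", sim), "shorter")
})

test_that("pwm scanning equals a brute-force window scan", {
  pwm <- make_test_pwm()
  withr::local_seed(9)
  region <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  lo <- log2(pwm$matrix / 0.25)
  brute <- function(s) {
    vapply(seq_len(nchar(s) - nrow(lo) + 1L), function(i) {
      w <- strsplit(substr(s, i, i + nrow(lo) - 1L), "")[[1]]
      sum(vapply(seq_along(w), function(j) lo[j, w[j]], 0))
    }, 0)
  }
  best <- max(c(brute(region), brute(eotrscan:::revcomp_chr(region))))
  smax <- sum(apply(lo, 1, max)); smin <- sum(apply(lo, 1, min))
  expect_equal(max_binding_wts(region, pwm),
               100 * (best - smin) / (smax - smin))
})

test_that("trap_profile: consensus occupancy, uniform PWM, r0 limits", {
  pwm <- make_test_pwm()
  L <- nrow(pwm$matrix)
  r0 <- exp(0.584 * L - 5.66)
  prof <- trap_profile(paste0("TTTT", eotrscan:::SIM_MOTIF, "TTTT"), pwm)
  expect_equal(max(prof), r0 / (1 + r0))
  upwm <- pwm_from_matrix(matrix(0.25, 6, 4))
  pu <- trap_profile("ACGTACGTACGTACGT", upwm)
  expect_true(all(abs(pu - pu[1]) < 1e-12))
  seqs <- "ACGTGACGTCAGTACGT"
  p_small <- trap_profile(seqs, pwm, r0 = 1e-8)
  p_big <- trap_profile(seqs, pwm, r0 = 1e-2)
  expect_true(all(p_small < p_big))   # strictly increasing in r0
  expect_true(all(p_small < 1e-6))
})

test_that("stap_fit recovers planted binding parameters", {
  pwm <- make_test_pwm()
  withr::local_seed(21)
  make_regions <- function(n) {
    vapply(seq_len(n), function(i) {
      ns <- sample(1:3, 1); nw <- sample(0:3, 1)
      parts <- c(rep(eotrscan:::SIM_MOTIF, ns),
                 rep(eotrscan:::SIM_MOTIF_WEAK, nw))
      fill <- paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                    collapse = "")
      paste0(fill, paste(parts, collapse = "TTTTT"), fill)
    }, "")
  }
  regions <- make_regions(40)
  strengths <- lapply(regions, eotrscan:::.site_strengths, pwm = pwm,
                      beta = 1 / 0.7)
  for (g in c(0.05, 2.0)) {
    intens <- predicted_occupancy(strengths, g)
    fit <- stap_fit(regions, intens, pwm)
    expect_lt(abs(fit$gamma - g) / g, 0.10)
    expect_gt(fit$exp_ratios, 0.99)
    expect_equal(fit$call, if (g > 1) "favorable" else "unfavorable")
  }
  expect_error(stap_fit(regions[1:5], 1:5, pwm), ">= 20")
  expect_error(stap_fit(regions, rep(1, 40), pwm), "degenerate")
})

test_that("stap_fit calls survive Poisson counting noise at the
          simulator's planted parameters", {
  pwm <- make_test_pwm()
  mk <- function(n) vapply(seq_len(n), function(i) {
    ns <- sample(1:3, 1); nw <- sample(0:3, 1)
    paste0(paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
           paste(c(rep(eotrscan:::SIM_MOTIF, ns),
                   rep(eotrscan:::SIM_MOTIF_WEAK, nw)),
                 collapse = "TTTTT"),
           paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""))
  }, "")
  ok <- vapply(1:30, function(rep) {
    set.seed(900 + rep)
    g <- if (rep %% 2 == 0) 2.0 else 0.2   # simulator's planted classes
    regions <- mk(40)
    st <- lapply(regions, eotrscan:::.site_strengths, pwm = pwm,
                 beta = 1 / 0.7)
    fit <- stap_fit(regions, rpois(40, 60 * predicted_occupancy(st, g)),
                    pwm)
    fit$call == (if (g > 1) "favorable" else "unfavorable")
  }, TRUE)
  expect_gte(mean(ok), 0.85)
})

test_that("permuted intensities destroy the fit correlation", {
  pwm <- make_test_pwm()
  withr::local_seed(4)
  regions <- vapply(1:30, function(i) {
    ns <- sample(1:3, 1)
    paste0(paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""),
           paste(rep(eotrscan:::SIM_MOTIF, ns), collapse = "TTT"),
           paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""))
  }, "")
  strengths <- lapply(regions, eotrscan:::.site_strengths, pwm = pwm,
                      beta = 1 / 0.7)
  intens <- predicted_occupancy(strengths, 2)
  rs <- replicate(50, {
    fit <- stap_fit(regions, sample(intens), pwm)
    fit$exp_ratios
  })
  expect_gt(mean(abs(rs) < 0.35), 0.9)
})

test_that("occlusion_threshold: separable case, tie rule, interleaving", {
  r <- occlusion_threshold(c(4, 4.5, 5, 1, 1.5, 2),
                           c(rep("unfavorable", 3), rep("favorable", 3)))
  expect_equal(r$threshold_cpm, 4)     # min unfavorable wins the tie
  expect_equal(r$separability, 0)
  # fully interleaved classes: best stump errs on the minority class
  x <- seq(1, 4, by = 0.5)
  cl <- rep(c("favorable", "unfavorable"), length.out = length(x))
  r2 <- occlusion_threshold(x, cl)
  expect_equal(r2$separability, min(table(cl)) / length(cl))
  expect_error(occlusion_threshold(1:3, rep("favorable", 3)), "both")
})
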