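test_that("jaccard_index matches per-base enumeration", {
  a <- intervals("toy", 0, 10)
  b <- intervals("toy", 5, 15)
  expect_equal(jaccard_index(a, a), 1.0)
  expect_equal(jaccard_index(a, intervals("toy", 50, 60)), 0.0)
  expect_equal(jaccard_index(a, b), 5 / 15)
  expect_error(jaccard_index(a, b, domain = intervals("toy", 5000, 6000)),
               "union")
  withr::local_seed(3)
  for (i in 1:25) {
    x <- random_set(sample(3:20, 1)); y <- random_set(sample(3:20, 1))
    expect_equal(jaccard_index(x, y),
                 sum(mask_of(x) & mask_of(y)) /
                   sum(mask_of(x) | mask_of(y)))
  }
  # symmetry and translation invariance
  expect_equal(jaccard_index(a, b), jaccard_index(b, a))
  shift <- function(g, d) intervals("toy", iv_start(g) + d, iv_end(g) + d)
  expect_equal(jaccard_index(shift(a, 100), shift(b, 100)),
               jaccard_index(a, b))
})

test_that("gsc_permutation: direction, minimum p, and determinism", {
  dom <- intervals("toy", 0, 10000)
  withr::local_seed(1)
  a <- random_set(12, max_w = 200)
  r <- gsc_permutation(a, a, dom, n_perm = 199, seed = 5)
  expect_equal(r$p_perm, 1 / 200)
  expect_false(r$smaller_than_chance)
  expect_true(r$p_perm >= 1 / (r$n_perm + 1))
  # constructed avoidance: b fills exactly the complement of a
  b <- subtract_sets(dom, a)
  r2 <- gsc_permutation(a, b, dom, n_perm = 199, seed = 5)
  expect_true(r2$smaller_than_chance)
  expect_equal(r2$jaccard, 0)
  # same seed, same result
  r3 <- gsc_permutation(a, b, dom, n_perm = 199, seed = 5)
  expect_equal(r2$p_perm, r3$p_perm)
  expect_error(gsc_permutation(a, b, dom, n_perm = 10), "n_perm")
})

test_that("relative distance is 0 at b-midpoints, 0.5 between them", {
  b <- intervals("toy", c(1000, 3000, 5000, 7000),
                 c(1200, 3200, 5200, 7200))
  at_mid <- intervals("toy", c(3090, 5090), c(3110, 5110))
  r <- relative_distance_ks(at_mid, b)
  expect_equal(r$reldist, c(0, 0))
  between <- intervals("toy", c(2090, 4090), c(2110, 4110))
  r2 <- relative_distance_ks(between, b)
  expect_equal(r2$reldist, c(0.5, 0.5))
  mixed_a <- suppressWarnings(c(at_mid, intervals("chrZ", 0, 10)))
  expect_warning(
    relative_distance_ks(mixed_a,
                         suppressWarnings(c(b, intervals("chrZ", 5, 6)))),
    "skipped")
})

test_that("chi2_counts matches the hand-computed Pearson statistic", {
  r0 <- chi2_counts(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$chi2, 0); expect_equal(r0$p, 1)
  r <- chi2_counts(matrix(c(30, 10, 10, 30), 2))
  expect_equal(r$chi2, 20.0)
  expect_error(chi2_counts(matrix(c(0, 0, 5, 5), 2)), "marginal")
  expect_error(chi2_counts(matrix(1:6, 2)), "2x2")
})

test_that("kl_pwm is zero iff identical, symmetric, matches closed form", {
  m <- matrix(c(0.85, 0.05, 0.05, 0.05,
                0.05, 0.85, 0.05, 0.05,
                0.05, 0.05, 0.85, 0.05,
                0.05, 0.05, 0.05, 0.85), 4, byrow = TRUE)
  expect_equal(kl_pwm(m, m)$sym_kl, 0)
  u <- matrix(0.25, 4, 4)
  # closed form at one position, replicated over four positions
  pc <- 1e-3
  p <- (m[1, ] + pc) / (1 + 4 * pc); q <- (u[1, ] + pc) / (1 + 4 * pc)
  expected <- (sum(p * log2(p / q)) + sum(q * log2(q / p))) / 2
  expect_equal(kl_pwm(m, u)$sym_kl, expected)
  expect_equal(kl_pwm(m, u)$sym_kl, kl_pwm(u, m)$sym_kl)
  expect_true(kl_pwm(m, u)$sym_kl > 0)
  expect_error(kl_pwm(m[1:3, ], m[1:3, ]), "length")
})
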