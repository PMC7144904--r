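# Genome-structure-corrected association statistics.
#
# The permutation null approximates the Genome Structure Correction by
# stratified circular rotation: within each analysis domain the b-features
# are rotated by an independent uniform offset, wrapping around the domain,
# which preserves feature lengths and spacing. The permutation loop runs on
# plain numeric start/end vectors for speed; the public API takes GRanges.

#' Base-pair Jaccard index of two interval sets
#'
#' Intersection over union in base pairs, optionally after clipping both
#' sets to a domain. An empty union is an error (the statistic is
#' undefined), matching the convention of genome-arithmetic tools.
#'
#' @param a,b `GRanges`.
#' @param domain optional `GRanges` to clip both sets to.
#' @return numeric in [0, 1].
#' @export
jaccard_index <- function(a, b, domain = NULL) {
  if (!is.null(domain)) {
    a <- intersection_footprint(a, domain)
    b <- intersection_footprint(b, domain)
  }
  a <- normalize_intervals(a); b <- normalize_intervals(b)
  inter <- total_width(GenomicRanges::intersect(a, b, ignore.strand = TRUE))
  uni <- total_width(GenomicRanges::union(a, b, ignore.strand = TRUE))
  if (uni == 0) stop("Jaccard undefined: empty union")
  inter / uni
}

# intersection length of two internally-disjoint interval lists (numeric)
.inter_len <- function(as, ae, bs, be) {
  if (length(as) == 0L || length(bs) == 0L) return(0)
  ov <- pmin(rep(ae, times = length(bs)), rep(be, each = length(as))) -
    pmax(rep(as, times = length(bs)), rep(bs, each = length(as)))
  sum(ov[ov > 0])
}

# rotate intervals within [d0, d1) by offset, splitting at the wrap point
.rotate_intervals <- function(s, e, d0, d1, offset) {
  L <- d1 - d0
  ns <- (s - d0 + offset) %% L
  ne <- ns + (e - s)
  wrap <- ne > L
  out_s <- c(ns[!wrap], ns[wrap], rep(0, sum(wrap)))
  out_e <- c(ne[!wrap], rep(L, sum(wrap)), ne[wrap] - L)
  keep <- out_e > out_s
  list(s = d0 + out_s[keep], e = d0 + out_e[keep])
}

#' Domain-stratified circular-rotation permutation test for interval overlap
#'
#' Computes the observed base-pair Jaccard of `a` and `b` clipped to the
#' analysis domains, then forms a null by rotating the `b` intervals within
#' each domain by independent uniform offsets. The one-sided p-value is
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`; `smaller_than_chance`
#' reports the GSC-style TRUE/FALSE direction (observed overlap below the
#' null median).
#'
#' @param a,b `GRanges` features.
#' @param domains `GRanges` partitioning the analysis space (e.g. intronic
#'   and intergenic blocks); features are clipped to them.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the rotation offsets.
#' @return list: `jaccard`, `p_perm`, `smaller_than_chance`, `n_perm`,
#'   `seed`, `null_median`.
#' @export
gsc_permutation <- function(a, b, domains, n_perm = 999, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  domains <- normalize_intervals(domains)
  a <- intersection_footprint(a, domains)
  b <- intersection_footprint(b, domains)
  if (length(a) == 0L || length(b) == 0L)
    stop("a or b empty within all domains")
  dchr <- as.character(GenomicRanges::seqnames(domains))
  d0 <- iv_start(domains); d1 <- iv_end(domains)
  achr <- as.character(GenomicRanges::seqnames(a))
  bchr <- as.character(GenomicRanges::seqnames(b))
  as_ <- iv_start(a); ae_ <- iv_end(a)
  bs_ <- iv_start(b); be_ <- iv_end(b)
  # assign each feature to its (single, post-clip) domain
  dom_of <- function(chr, s, e) {
    idx <- rep(NA_integer_, length(s))
    for (k in seq_along(d0)) {
      hit <- chr == dchr[k] & s >= d0[k] & e <= d1[k]
      idx[hit & is.na(idx)] <- k
    }
    if (anyNA(idx)) stop("feature not contained in any single domain")
    idx
  }
  adom <- dom_of(achr, as_, ae_)
  bdom <- dom_of(bchr, bs_, be_)
  len_a <- sum(ae_ - as_); len_b <- sum(be_ - bs_)
  obs_inter <- sum(vapply(seq_along(d0), function(k) {
    .inter_len(as_[adom == k], ae_[adom == k],
               bs_[bdom == k], be_[bdom == k])
  }, 0))
  obs <- obs_inter / (len_a + len_b - obs_inter)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  null_inter <- numeric(n_perm)
  for (k in seq_along(d0)) {
    ak <- adom == k; bk <- bdom == k
    if (!any(ak) || !any(bk)) next
    L <- d1[k] - d0[k]
    offsets <- runif(n_perm, 0, L)
    # all rotations at once: each rotated b interval is at most two
    # pieces (wrap split), held as n_perm x nb matrices of local coords
    s0 <- bs_[bk] - d0[k]; w <- be_[bk] - bs_[bk]
    S1 <- outer(offsets, s0, `+`) %% L
    E1raw <- sweep(S1, 2, w, `+`)
    E1 <- pmin(E1raw, L)
    E2 <- pmax(E1raw - L, 0)     # wrapped piece is [0, E2)
    a_s <- as_[ak] - d0[k]; a_e <- ae_[ak] - d0[k]
    for (i in seq_along(a_s)) {
      ov1 <- pmin(E1, a_e[i]) - pmax(S1, a_s[i])
      ov1[ov1 < 0] <- 0
      ov2 <- pmin(E2, a_e[i]) - a_s[i]
      ov2[ov2 < 0] <- 0
      null_inter <- null_inter + rowSums(ov1) + rowSums(ov2)
    }
  }
  null_j <- null_inter / (len_a + len_b - null_inter)
  p <- (1 + sum(null_j >= obs)) / (n_perm + 1)
  list(jaccard = obs, p_perm = p,
       smaller_than_chance = obs < median(null_j),
       n_perm = n_perm, seed = seed, null_median = median(null_j))
}

#' Relative-distance distribution and KS test against Uniform(0, 0.5)
#'
#' For each midpoint of `a`, the relative distance is the distance to the
#' nearest `b` midpoint divided by the distance between the two flanking
#' `b` midpoints; under spatial independence it is Uniform(0, 0.5).
#' `a` features outside the span of `b` midpoints on their chromosome, and
#' chromosomes with fewer than two `b` features, are skipped (the latter
#' with a warning).
#'
#' @param a,b `GRanges`.
#' @return list: `reldist` (numeric vector), `ks_stat`, `p`.
#' @export
relative_distance_ks <- function(a, b) {
  achr <- as.character(GenomicRanges::seqnames(a))
  bchr <- as.character(GenomicRanges::seqnames(b))
  amid <- (iv_start(a) + iv_end(a)) / 2
  bmid <- (iv_start(b) + iv_end(b)) / 2
  rel <- numeric(0)
  for (chr in unique(achr)) {
    bm <- sort(bmid[bchr == chr])
    if (length(bm) < 2L) {
      warning("chromosome ", chr, " has < 2 b features; skipped")
      next
    }
    am <- amid[achr == chr]
    am <- am[am >= bm[1] & am <= bm[length(bm)]]
    if (length(am) == 0L) next
    idx <- findInterval(am, bm, rightmost.closed = TRUE,
                        all.inside = TRUE)
    left <- bm[idx]; right <- bm[idx + 1L]
    rel <- c(rel, pmin(am - left, right - am) / (right - left))
  }
  if (length(rel) == 0L) stop("no relative distances computable")
  ks <- suppressWarnings(stats::ks.test(rel, stats::punif, 0, 0.5))
  list(reldist = rel, ks_stat = unname(ks$statistic), p = ks$p.value)
}

#' Pearson chi-squared test on a 2x2 count table
#'
#' Without continuity correction (the comparisons it serves involve large
#' peak counts). Zero expected cells are an error.
#'
#' @param table 2x2 numeric matrix of counts.
#' @param correct apply the Yates correction (default `FALSE`).
#' @return list: `chi2`, `p`, `df`.
#' @export
chi2_counts <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be >= 0")
  n <- sum(table)
  if (n == 0) stop("empty table")
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(expected == 0)) stop("zero marginal: expected count 0")
  dev <- abs(table - expected)
  if (correct) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Symmetrized per-position Kullback-Leibler divergence of two PWMs
#'
#' PWMs are truncated to the shorter length at the offset maximizing the
#' column-wise Pearson correlation of their probability matrices; entries
#' are pseudocounted and renormalized before the divergence (in bits) is
#' averaged over positions.
#'
#' @param pwm_a,pwm_b PWM objects (see [pwm_from_sites()]) or plain L x 4
#'   probability matrices.
#' @param pseudocount added to every cell before renormalization.
#' @return list: `sym_kl` (bits, >= 0), `length_used`, `pseudocount`,
#'   `offset`.
#' @export
kl_pwm <- function(pwm_a, pwm_b, pseudocount = 1e-3) {
  ma <- if (is.list(pwm_a)) pwm_a$matrix else pwm_a
  mb <- if (is.list(pwm_b)) pwm_b$matrix else pwm_b
  if (nrow(ma) > nrow(mb)) { tmp <- ma; ma <- mb; mb <- tmp }
  L <- nrow(ma)
  if (L < 4L) stop("PWM length < 4")
  offsets <- 0:(nrow(mb) - L)
  score <- vapply(offsets, function(o)
    suppressWarnings(stats::cor(
      as.vector(ma), as.vector(mb[(o + 1):(o + L), , drop = FALSE]))), 0)
  score[is.na(score)] <- -Inf   # zero-variance matrices carry no signal
  o <- offsets[which.max(score)]
  if (length(o) == 0L) o <- 0L
  mb <- mb[(o + 1):(o + L), , drop = FALSE]
  pc <- function(m) {
    m <- m + pseudocount
    m / rowSums(m)
  }
  p <- pc(ma); q <- pc(mb)
  kl <- rowSums(p * log2(p / q)) + rowSums(q * log2(q / p))
  list(sym_kl = mean(kl) / 2, length_used = L, pseudocount = pseudocount,
       offset = o)
}
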