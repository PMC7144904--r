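# Count normalization and simplified differential calls.
#
# edgeR's TMM/GLM machinery is deliberately replaced by median-of-ratios
# scaling plus a pooled label-permutation test on a moderated t-like
# statistic: with three replicates per side only 20 distinct label
# assignments exist, so per-feature permutation p-values cannot fall below
# 0.05; pooling the permuted statistics across features (SAM-style) gives
# the resolution the fold-change classes need. The {-1, 0, +1} classes
# require |L2FC| > threshold AND BH-adjusted q < alpha.

#' Median-of-ratios size factors
#'
#' Per-sample median of count ratios to the feature-wise geometric mean
#' (features with a zero are excluded), rescaled to geometric mean 1.
#'
#' @param counts matrix (features x samples).
#' @return numeric size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts == 0) == 0L
  if (!any(keep)) return(rep(1, ncol(counts)))
  lg <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2, stats::median))
  sf / exp(mean(log(sf)))
}

#' Counts-per-million normalization
#'
#' `cpm = count / (library_size * size_factor / 1e6)`, with size factors
#' from [size_factors()] (or 1 when `scale = FALSE`). Library sizes
#' default to column sums.
#'
#' @param counts matrix (features x samples).
#' @param library_sizes per-sample total mapped reads (> 0).
#' @param scale apply median-of-ratios scaling (default `TRUE`).
#' @return numeric CPM matrix.
#' @export
cpm_normalize <- function(counts, library_sizes = NULL, scale = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  sf <- if (scale) size_factors(counts) else rep(1, ncol(counts))
  sweep(counts, 2, library_sizes * sf / 1e6, "/")
}

#' Common biological coefficient of variation
#'
#' Method-of-moments common negative-binomial dispersion across features
#' (on CPM-equalized counts within replicate groups):
#' `phi = sum(v - m) / sum(m^2)` pooled over features, floored at 0;
#' `bcv = sqrt(phi)`.
#'
#' @param counts matrix (features x samples).
#' @param groups factor of sample groups; at least one group needs >= 2
#'   replicates.
#' @return numeric BCV (>= 0).
#' @export
estimate_bcv <- function(counts, groups) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  reps <- table(groups)
  if (!any(reps >= 2L)) stop("no replicated group: BCV inestimable")
  num <- 0; den <- 0
  for (g in names(reps)[reps >= 2L]) {
    sub <- counts[, groups == g, drop = FALSE]
    # equalize depths so library-size differences do not inflate phi
    sub <- sweep(sub, 2, colSums(sub) / mean(colSums(sub)), "/")
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    ok <- m > 0
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  sqrt(max(0, num / den))
}

moderated_stat <- function(case_cpm, ctrl_cpm, s0) {
  m1 <- rowMeans(case_cpm); m2 <- rowMeans(ctrl_cpm)
  n1 <- ncol(case_cpm); n2 <- ncol(ctrl_cpm)
  v1 <- if (n1 > 1) apply(case_cpm, 1, stats::var) else 0
  v2 <- if (n2 > 1) apply(ctrl_cpm, 1, stats::var) else 0
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) /
               max(1, n1 + n2 - 2) * (1 / n1 + 1 / n2))
  (m1 - m2) / (sp + s0)
}

#' Differential occupancy / expression call with fold-change classes
#'
#' Log2 fold changes on CPM with a 0.5 pseudocount; p-values by pooled
#' label permutation of a variance-moderated statistic; BH adjustment;
#' `fc_class = +1` iff `l2fc > l2fc_threshold` and `q < alpha` (`-1`
#' symmetric, else `0`). With a single sample per side only fold changes
#' are computed (`p = q = NA`, classes from the fold change alone).
#'
#' @param counts_case,counts_control matrices (features x samples) with
#'   identical row names.
#' @param l2fc_threshold log2 fold-change threshold (default 1.5).
#' @param alpha q-value threshold (default 0.05).
#' @param n_perm number of label permutations (default 1000; capped at the
#'   number of distinct assignments).
#' @param seed integer seed.
#' @param library_sizes optional named/ordered sizes for
#'   `cbind(case, control)`.
#' @param scale apply median-of-ratios scaling; set `FALSE` when the
#'   columns share one library (e.g. allele layers), where a genuine
#'   global shift must not be normalized away.
#' @return data.frame: `feature`, `l2fc`, `p`, `q`, `fc_class`, `bcv`.
#' @export
differential_call <- function(counts_case, counts_control,
                              l2fc_threshold = 1.5, alpha = 0.05,
                              n_perm = 1000, seed = 1,
                              library_sizes = NULL, scale = TRUE) {
  counts_case <- as.matrix(counts_case)
  counts_control <- as.matrix(counts_control)
  if (nrow(counts_case) != nrow(counts_control))
    stop("case and control must share features")
  all_counts <- cbind(counts_case, counts_control)
  n1 <- ncol(counts_case); n2 <- ncol(counts_control)
  cpm <- cpm_normalize(all_counts, library_sizes, scale = scale)
  l2fc <- log2((rowMeans(cpm[, seq_len(n1), drop = FALSE]) + 0.5) /
                 (rowMeans(cpm[, n1 + seq_len(n2), drop = FALSE]) + 0.5))
  bcv <- tryCatch(estimate_bcv(all_counts,
                               rep(c("case", "ctrl"), c(n1, n2))),
                  error = function(e) NA_real_)
  feat <- rownames(all_counts) %||% as.character(seq_len(nrow(all_counts)))
  if (n1 < 2L || n2 < 2L) {
    cls <- ifelse(l2fc > l2fc_threshold, 1L,
                  ifelse(l2fc < -l2fc_threshold, -1L, 0L))
    return(data.frame(feature = feat, l2fc = l2fc, p = NA_real_,
                      q = NA_real_, fc_class = cls, bcv = bcv,
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  s0 <- stats::median(apply(cpm, 1, stats::sd)) * 0.1 + 1e-8
  obs <- moderated_stat(cpm[, seq_len(n1), drop = FALSE],
                        cpm[, n1 + seq_len(n2), drop = FALSE], s0)
  combos <- utils::combn(n1 + n2, n1)
  # drop the identity and (for equal sizes) complement assignments: they
  # reproduce +/- the observed statistic and would floor the pooled p
  is_id <- apply(combos, 2, function(ix) all(ix == seq_len(n1)))
  is_comp <- if (n1 == n2)
    apply(combos, 2, function(ix) all(ix == n1 + seq_len(n2)))
  else rep(FALSE, ncol(combos))
  combos <- combos[, !(is_id | is_comp), drop = FALSE]
  if (ncol(combos) > n_perm) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    combos <- combos[, sample.int(ncol(combos), n_perm), drop = FALSE]
  }
  null_stats <- unlist(lapply(seq_len(ncol(combos)), function(j) {
    idx <- combos[, j]
    moderated_stat(cpm[, idx, drop = FALSE],
                   cpm[, -idx, drop = FALSE], s0)
  }))
  null_abs <- abs(null_stats)
  p <- (1 + vapply(abs(obs), function(s) sum(null_abs >= s), 0)) /
    (length(null_abs) + 1)
  q <- stats::p.adjust(p, method = "BH")
  cls <- ifelse(l2fc > l2fc_threshold & q < alpha, 1L,
                ifelse(l2fc < -l2fc_threshold & q < alpha, -1L, 0L))
  zero <- rowSums(all_counts) == 0
  p[zero] <- 1; q[zero] <- 1; cls[zero] <- 0L
  data.frame(feature = feat, l2fc = l2fc, p = p, q = q, fc_class = cls,
             bcv = bcv, stringsAsFactors = FALSE, row.names = NULL)
}
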