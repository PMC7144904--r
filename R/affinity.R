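# Thermodynamic TF-affinity modelling.
#
# A PWM is scored as log2 odds against a uniform background. Mismatch
# energies relative to the best attainable site feed a TRAP-style occupancy
# p_i = R0 exp(-E_i) / (1 + R0 exp(-E_i)) with lambda = 0.7 and
# ln R0 = 0.584 L - 5.66 by default. The binding-parameter fit is a
# single-TF, no-cooperativity reimplementation of the STAP idea: predicted
# region occupancy N_r(gamma) = sum_i gamma a_i / (1 + gamma a_i) with
# a_i = exp(-E_i), gamma fitted by 1-D search on log10 gamma in [-6, 6]
# minimizing the SSE between z-scored predictions and z-scored observed
# ChIP intensities. gamma > 1 is a favorable (stronger-than-reference)
# interaction, gamma < 1 unfavorable.

BASES <- c("A", "C", "G", "T")

#' Build a PWM from aligned binding sites
#'
#' Column base frequencies with a pseudocount, renormalized per position.
#'
#' @param sites character vector of equal-length A/C/G/T sequences (>= 10).
#' @param pseudocount added to each base count (default 0.5).
#' @param name motif name.
#' @return list of class `pwm`: `matrix` (L x 4, rows sum to 1), `name`,
#'   `pseudocount`.
#' @export
pwm_from_sites <- function(sites, pseudocount = 0.5, name = "motif") {
  if (length(sites) < 10L) stop("need >= 10 aligned sites")
  L <- unique(nchar(sites))
  if (length(L) != 1L) stop("sites differ in length")
  chars <- matrix(unlist(strsplit(toupper(sites), "")), ncol = L,
                  byrow = TRUE)
  if (!all(chars %in% BASES)) stop("sites must be A/C/G/T only")
  m <- vapply(seq_len(L), function(j)
    tabulate(factor(chars[, j], BASES), 4L), numeric(4))
  m <- t(m + pseudocount)
  m <- m / rowSums(m)
  colnames(m) <- BASES
  structure(list(matrix = m, name = name, pseudocount = pseudocount),
            class = "pwm")
}

#' Build a PWM directly from a probability matrix
#' @param matrix L x 4 matrix of base probabilities (columns A,C,G,T).
#' @param name motif name.
#' @return a `pwm`.
#' @export
pwm_from_matrix <- function(matrix, name = "motif") {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stop("PWM matrix must have 4 columns")
  if (any(matrix <= 0)) stop("PWM entries must be > 0 (pseudocount first)")
  if (any(abs(rowSums(matrix) - 1) > 1e-9)) stop("PWM rows must sum to 1")
  colnames(matrix) <- BASES
  structure(list(matrix = matrix, name = name, pseudocount = 0),
            class = "pwm")
}

seq_to_idx <- function(sequence) {
  idx <- match(strsplit(toupper(sequence), "")[[1]], BASES)
  idx
}

# log2-odds score of every window on one strand; NA bases score 0 per column
.scan_scores <- function(idx, lodds) {
  L <- nrow(lodds)
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    col <- lodds[j, ][idx[j:(j + n - 1L)]]
    col[is.na(col)] <- 0
    sc <- sc + col
  }
  sc
}

pwm_logodds <- function(pwm) log2(pwm$matrix / 0.25)

revcomp_chr <- function(sequence)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))

#' Log2-odds PWM score of a single window
#' @param window sequence of exactly the motif length.
#' @param pwm a `pwm`.
#' @return numeric log2-odds score against a uniform background.
#' @export
pwm_score <- function(window, pwm) {
  lo <- pwm_logodds(pwm)
  if (nchar(window) != nrow(lo)) stop("window length must equal PWM length")
  s <- .scan_scores(seq_to_idx(window), lo)
  s
}

# best-window log2-odds over both strands
.best_score <- function(sequence, pwm) {
  lo <- pwm_logodds(pwm)
  if (nchar(sequence) < nrow(lo)) stop("region shorter than the motif")
  max(.scan_scores(seq_to_idx(sequence), lo),
      .scan_scores(seq_to_idx(revcomp_chr(sequence)), lo))
}

#' Scaled best PWM score of a region (maxBindingWts analogue)
#'
#' Scans both strands and rescales the best window log-odds to [0, 100]
#' between the worst and best achievable site scores, so a region carrying
#' the consensus scores 100 and a pure anti-consensus region scores 0.
#'
#' @param region A/C/G/T sequence (length >= motif length).
#' @param pwm a `pwm`.
#' @return numeric in [0, 100].
#' @export
max_binding_wts <- function(region, pwm) {
  lo <- pwm_logodds(pwm)
  smax <- sum(apply(lo, 1, max)); smin <- sum(apply(lo, 1, min))
  100 * (.best_score(region, pwm) - smin) / (smax - smin)
}

#' TRAP-style per-position occupancy profile
#'
#' Mismatch energy `E_i = beta * (S_best - S_i)` from the PWM log-odds of
#' window i relative to the best attainable site; occupancy
#' `p_i = r0 exp(-E_i) / (1 + r0 exp(-E_i))`, maximum over strands.
#'
#' @param sequence A/C/G/T sequence.
#' @param pwm a `pwm`.
#' @param beta inverse mismatch-energy scale (default 1/0.7).
#' @param r0 reference binding constant; default `exp(0.584 * L - 5.66)`.
#' @return numeric vector of occupancies, one per window start.
#' @export
trap_profile <- function(sequence, pwm, beta = 1 / 0.7, r0 = NULL) {
  lo <- pwm_logodds(pwm)
  L <- nrow(lo)
  if (is.null(r0)) r0 <- exp(0.584 * L - 5.66)
  smax <- sum(apply(lo, 1, max))
  fwd <- .scan_scores(seq_to_idx(sequence), lo)
  rev <- rev(.scan_scores(seq_to_idx(revcomp_chr(sequence)), lo))
  s <- pmax(fwd, rev)
  w <- r0 * exp(-beta * (smax - s))
  w / (1 + w)
}

# site strengths a_i = exp(-E_i) per window (both strands, max)
.site_strengths <- function(sequence, pwm, beta) {
  lo <- pwm_logodds(pwm)
  smax <- sum(apply(lo, 1, max))
  fwd <- .scan_scores(seq_to_idx(sequence), lo)
  rev <- rev(.scan_scores(seq_to_idx(revcomp_chr(sequence)), lo))
  exp(-beta * (smax - pmax(fwd, rev)))
}

#' Predicted region occupancy at a binding parameter gamma
#' @param strengths list of per-region site-strength vectors.
#' @param gamma binding parameter.
#' @return numeric vector of predicted occupancies per region.
#' @export
predicted_occupancy <- function(strengths, gamma) {
  vapply(strengths, function(a) sum(gamma * a / (1 + gamma * a)), 0)
}

#' Fit the relative binding parameter of a TF over a region set
#'
#' Fits gamma (the STAP `inFactorIntMat` analogue) by 1-D search over
#' `log10(gamma) in [-6, 6]` (coarse grid plus local refinement). The
#' default objective is the Poisson deviance between observed intensities
#' and `c * N_r(gamma)` with the scale `c` profiled out in closed form:
#' the fit stays a *relative* measure but weights low-count regions
#' appropriately, which keeps the estimate centred where the z-scored SSE
#' objective drifts (occupancy is nearly proportional to site content at
#' small gamma, and a scale-free SSE cannot see a pure scaling).
#' `objective = "zsse"` selects the plain z-scored SSE. The call is
#' `"favorable"` iff gamma > 1.
#'
#' @param sequences character vector of region sequences (>= 20).
#' @param intensities observed ChIP intensities (>= 0), one per region.
#' @param pwm a `pwm`.
#' @param beta TRAP energy scale (default 1/0.7).
#' @param objective `"poisson"` (profiled-scale deviance, default) or
#'   `"zsse"` (SSE on z-scores).
#' @return list of class `stap_fit`: `gamma` (in_factor_int_mat),
#'   `exp_ratios` (Pearson r at the fit), `max_binding_wts` (mean scaled
#'   best score over regions), `call`, `objective`, `deviance`.
#' @export
stap_fit <- function(sequences, intensities, pwm, beta = 1 / 0.7,
                     objective = c("poisson", "zsse")) {
  objective <- match.arg(objective)
  if (length(sequences) < 20L) stop("need >= 20 regions")
  if (length(intensities) != length(sequences))
    stop("one intensity per region required")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  if (stats::sd(intensities) == 0)
    stop("degenerate fit: observed intensities are constant")
  strengths <- lapply(sequences, .site_strengths, pwm = pwm, beta = beta)
  zobs <- scale(intensities)[, 1]
  y <- intensities
  obj <- if (objective == "zsse") function(lg) {
    pred <- predicted_occupancy(strengths, 10^lg)
    if (stats::sd(pred) == 0) return(sum(zobs^2))
    sum((scale(pred)[, 1] - zobs)^2)
  } else function(lg) {
    n <- predicted_occupancy(strengths, 10^lg)
    if (all(n == 0)) return(Inf)
    mu <- pmax(sum(y) / sum(n) * n, 1e-12)
    2 * sum(mu - y + ifelse(y > 0, y * log(y / mu), 0))
  }
  grid <- seq(-6, 6, by = 0.1)
  vals <- vapply(grid, obj, 0)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-6)
  gamma <- 10^opt$minimum
  pred <- predicted_occupancy(strengths, gamma)
  r <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, intensities)
  structure(list(gamma = gamma, in_factor_int_mat = gamma,
                 exp_ratios = r,
                 max_binding_wts = mean(vapply(sequences, max_binding_wts,
                                               0, pwm = pwm)),
                 call = if (gamma > 1) "favorable" else "unfavorable",
                 objective = objective, deviance = opt$objective),
            class = "stap_fit")
}

#' Expression threshold separating occluding from non-occluding transcripts
#'
#' Decision stump over log2 CPM: transcripts at or above the threshold are
#' predicted to occlude (unfavorable binding), below it not to. Candidate
#' cuts are the observed expression values; the minimum-misclassification
#' cut is returned, ties broken toward the minimum expression observed among
#' unfavorable-associated transcripts.
#'
#' @param log2_cpm numeric expression values (log2 CPM).
#' @param call character, `"favorable"` or `"unfavorable"` per transcript.
#' @return list: `threshold_cpm` (log2 scale), `separability` (fraction
#'   misclassified at the threshold).
#' @export
occlusion_threshold <- function(log2_cpm, call) {
  call <- as.character(call)
  if (!all(call %in% c("favorable", "unfavorable")))
    stop("call must be favorable/unfavorable")
  if (length(unique(call)) < 2L)
    stop("both favorable and unfavorable calls required")
  # the sentinel cut above the maximum realizes the all-favorable stump
  cuts <- c(sort(unique(log2_cpm)), max(log2_cpm) + 1)
  err <- vapply(cuts, function(t)
    sum((log2_cpm >= t) != (call == "unfavorable")), 0)
  best <- cuts[err == min(err)]
  min_unfav <- min(log2_cpm[call == "unfavorable"])
  thr <- if (min_unfav %in% best) min_unfav else best[1L]
  list(threshold_cpm = thr, separability = min(err) / length(call))
}
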