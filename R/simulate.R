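# Synthetic-locus generator with planted ground truth.
#
# A small genome is tiled into 6 kb locus slots holding five classes:
#   eotr            capped/polyadenylated transcript across an enhancer,
#                   H3K4me3+CAGE promoter, H3K36me3 body, occluded TFBSs
#                   (weak planted binding parameter), polymerase pausing,
#                   attenuated acetylation, few loops (to poised promoters)
#   erna            acetylated enhancer transcribing a short non-polyA RNA,
#                   no H3K36me3/H3K4me3, strong TFBS binding, no pausing,
#                   many loops (to active promoters)
#   inert           H3K4me1+p300 enhancer without acetylation or transcript
#   mrna_like       candidate identical to a known gene (coding ORF planted)
#   intron_fragment candidate inside a known gene's intron, no promoter
#                   signatures
# All randomness flows from config$seed; a rerun is byte-identical.
#
# The TFBS emission rate of the pausing profile is solved from the
# piecewise-constant expectation so that feature_mean / domain_mean equals
# config$pausing_ratio exactly in expectation. TF ChIP intensities are
# drawn from the thermodynamic occupancy model at the planted gamma
# (occluded gamma = chip_tf_attenuation * gamma_active): a pure intensity
# scaling would be invisible to the scale-free affinity fit.

SIM_MOTIF <- "TGACGTCA"
SIM_MOTIF_WEAK <- "CGACGTCA"  # one mismatch at the low-information position

# Graded PWM for the simulated TF: two low-information positions (0.4 for
# the consensus base) followed by six near-deterministic ones (0.85). The
# mix of exact-consensus (strong) and position-1-mismatch (weak) planted
# sites makes the binding parameter identifiable from region occupancies:
# with homogeneous sites the occupancy would be proportional to copy
# number at every gamma and the scale-free fit would be degenerate.
sim_pwm <- function() {
  L <- nchar(SIM_MOTIF)
  m <- matrix(0.05, L, 4, dimnames = list(NULL, BASES))
  for (j in seq_len(L)) m[j, substr(SIM_MOTIF, j, j)] <- 0.85
  m[1:2, ] <- 0.2
  for (j in 1:2) m[j, substr(SIM_MOTIF, j, j)] <- 0.4
  pwm_from_matrix(m / rowSums(m), name = "simTF")
}

#' Simulator configuration
#'
#' Defaults encode the stated world: 60 planted EOTrs among 300 candidate
#' transcripts, log2 CPM 3-6 for EOTrs vs 0.42-1.70 for eRNAs, pausing
#' ratio 5, allelic imbalance 0.8, 4 loops per active vs 1 per occluded
#' enhancer.
#'
#' @param seed integer; fixes every random draw.
#' @param n_chroms,chrom_length genome shape (default 2 x 2 Mb).
#' @param n_eotr,n_erna,n_inert,n_mrna_like,n_intron_fragment locus counts.
#' @param h3k27ac_attenuation acetylation count attenuation at EOTr
#'   enhancers, in (0, 1].
#' @param chip_tf_attenuation occluded binding-parameter fraction in
#'   (0, 1]: gamma_occluded = chip_tf_attenuation * gamma_active.
#' @param gamma_active planted binding parameter at control TFBSs.
#' @param pausing_ratio planted TFBS pausing index (>= 1).
#' @param eotr_cpm_range,erna_cpm_range log2 CPM ranges.
#' @param ase_imbalance reference-allele read fraction at EOTr SNVs.
#' @param allele_activity_fold H3K27ac fold excess on the EOTr-free allele.
#' @param loops_per_active_enhancer,loops_per_occluded_enhancer loop counts.
#' @param nb_dispersion negative-binomial dispersion for count matrices.
#' @param coverage_depth mean GRO-seq signal per 10 bp bin over transcribed
#'   domains.
#' @param tss_peak_fold TSS peak enrichment of the polymerase profile.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_chroms = 2, chrom_length = 2e6,
                       n_eotr = 60, n_erna = 80, n_inert = 60,
                       n_mrna_like = 80, n_intron_fragment = 80,
                       h3k27ac_attenuation = 0.4,
                       chip_tf_attenuation = 0.1, gamma_active = 2.0,
                       pausing_ratio = 5.0,
                       eotr_cpm_range = c(3.0, 6.0),
                       erna_cpm_range = c(0.4, 1.7),
                       ase_imbalance = 0.8, allele_activity_fold = 8,
                       loops_per_active_enhancer = 4,
                       loops_per_occluded_enhancer = 1,
                       nb_dispersion = 0.1, coverage_depth = 50,
                       tss_peak_fold = 4) {
  cfg <- as.list(environment())
  if (h3k27ac_attenuation <= 0 || h3k27ac_attenuation > 1 ||
      chip_tf_attenuation <= 0 || chip_tf_attenuation > 1)
    stop("attenuations must be in (0, 1]")
  if (pausing_ratio < 1) stop("pausing_ratio must be >= 1")
  slot <- 6000
  n_slots <- n_eotr + n_erna + n_inert + n_mrna_like + n_intron_fragment
  if (slot > chrom_length)
    stop("config error: locus slot larger than the chromosome")
  if (n_slots * slot > n_chroms * chrom_length)
    stop("config error: loci do not fit the genome")
  cfg$slot <- slot
  class(cfg) <- "sim_config"
  cfg
}

# map a local [u1, u2) interval (or point u1 with u2 = u1 + 1) into genome
# coordinates, mirroring for minus-strand loci
.map_u <- function(slot_start, slot_len, strand, u1, u2) {
  if (strand == "+") c(slot_start + u1, slot_start + u2)
  else c(slot_start + slot_len - u2, slot_start + slot_len - u1)
}

.rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                               collapse = "")

.codons <- function() {
  all3 <- do.call(paste0, expand.grid(BASES, BASES, BASES))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

.rnbinom2 <- function(n, mu, disp) {
  if (disp <= 0) rpois(n, mu) else rnbinom(n, size = 1 / disp, mu = mu)
}

#' Generate the synthetic genome, all derived files and the truth table
#'
#' Writes `genome.fa`, per-mark peak BEDs under `marks/`,
#' `transcripts.gtf` (candidates), `refseq.gtf` (known genes), `cage.bed`,
#' `groseq.bedgraph`, `tfbs.bed`, `tf_counts.tsv`, `rna_counts.tsv`,
#' `h3k27ac_counts.tsv`, `h3k27ac_allele_counts.tsv`, `ase_counts.tsv`,
#' `loops.bedpe` and `truth.tsv` into `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `truth` (data.frame), `dir`, and `files`.
#' @export
simulate_loci <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(file.path(out_dir, "marks"), recursive = TRUE,
             showWarnings = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  genome <- lapply(chroms, function(ch)
    sample(BASES, cfg$chrom_length, replace = TRUE))
  names(genome) <- chroms

  classes <- rep(c("eotr", "erna", "inert", "mrna_like",
                   "intron_fragment"),
                 c(cfg$n_eotr, cfg$n_erna, cfg$n_inert, cfg$n_mrna_like,
                   cfg$n_intron_fragment))
  n_loci <- length(classes)
  # round-robin slot assignment across chromosomes
  chrom_of <- chroms[(seq_len(n_loci) - 1L) %% cfg$n_chroms + 1L]
  slot_idx <- ((seq_len(n_loci) - 1L) %/% cfg$n_chroms)
  slot_start <- slot_idx * cfg$slot
  strand_of <- sample(c("+", "-"), n_loci, replace = TRUE)
  strand_of[classes %in% c("mrna_like", "intron_fragment")] <- "+"

  marks <- c("h3k4me1", "h3k4me3", "h3k4me2", "h3k36me3", "h3k27ac",
             "h3k9ac", "h3k27me3", "p300", "rnapii", "ctcf")
  mk <- setNames(lapply(marks, function(x)
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character())), marks)
  add_mark <- function(mark, chrom, se, name) {
    mk[[mark]] <<- rbind(mk[[mark]],
                         data.frame(chrom = chrom, start = se[1],
                                    end = se[2], name = name))
  }
  gtf_cand <- list(); gtf_known <- list()
  cage <- list(); tfbs <- list(); tfc <- list()
  gro <- list(); loops <- list(); ase <- list()
  truth <- list()
  rna_mu <- list()
  h3k27ac_mu <- list()
  allele_loci <- character()

  pwm <- sim_pwm()

  gamma_occ <- cfg$chip_tf_attenuation * cfg$gamma_active
  codons <- .codons()

  plant <- function(chrom, at0, s) {
    # overwrite genome[[chrom]] at 0-based position at0 with sequence s
    genome[[chrom]][(at0 + 1):(at0 + nchar(s))] <<-
      strsplit(s, "")[[1]]
  }
  region_seq <- function(chrom, s, e)
    paste(genome[[chrom]][(s + 1):e], collapse = "")

  # pausing-profile rates solved so that E[feature]/E[domain] = ratio
  W <- 2000; w_tss <- 200; w_f <- 200; w_rest <- W - w_tss - w_f
  M <- cfg$coverage_depth
  denom <- W - cfg$pausing_ratio * w_f
  if (denom <= 0) stop("pausing_ratio too large for the locus geometry")
  r_b <- M * denom / (cfg$tss_peak_fold * w_tss + w_rest)
  r_t <- cfg$tss_peak_fold * r_b
  r_f <- cfg$pausing_ratio * M

  add_gro <- function(chrom, se, rate_per_bin) {
    # Poisson per 10 bp bin at the given expected value
    nbin <- (se[2] - se[1]) %/% 10
    vals <- rpois(nbin, rate_per_bin)
    gro[[length(gro) + 1L]] <<- data.frame(
      chrom = chrom, start = se[1] + (seq_len(nbin) - 1L) * 10,
      end = se[1] + seq_len(nbin) * 10, value = vals)
  }

  known_genes <- list()  # promoter anchors for loops, per activity state

  plant_tfbs <- function(ch, se, tid, tf, locus_id, gamma, class_label) {
    n_strong <- sample(1:3, 1); n_weak <- sample(0:3, 1)
    motifs <- c(rep(SIM_MOTIF, n_strong), rep(SIM_MOTIF_WEAK, n_weak))
    for (cpy in seq_along(motifs))
      plant(ch, se[1] + 2 + (cpy - 1) * 15, motifs[cpy])
    tfbs[[length(tfbs) + 1L]] <<- data.frame(
      chrom = ch, start = se[1], end = se[2], name = tid, tf = tf)
    a <- .site_strengths(region_seq(ch, se[1], se[2]), pwm, 1 / 0.7)
    occ <- sum(gamma * a / (1 + gamma * a))
    tfc[[length(tfc) + 1L]] <<- data.frame(
      tfbs_id = tid, tf = tf, locus = locus_id, class = class_label,
      chrom = ch, start = se[1], end = se[2],
      count = rpois(1, 60 * occ))
  }

  for (i in seq_len(n_loci)) {
    cls <- classes[i]; ch <- chrom_of[i]; S <- slot_start[i]
    st <- strand_of[i]
    id <- sprintf("%s_%03d", cls, i)
    U <- function(u1, u2) .map_u(S, cfg$slot, st, u1, u2)
    t_truth <- data.frame(locus = id, class = cls, chrom = ch,
                          strand = st, enh_start = NA_real_,
                          enh_end = NA_real_, tx_id = NA_character_,
                          tss = NA_real_, tts = NA_real_,
                          cpm_log2 = NA_real_, allelic = FALSE,
                          n_loops = 0L, gamma = NA_real_,
                          pausing_ratio = NA_real_)
    if (cls %in% c("eotr", "erna", "inert")) {
      add_mark("h3k4me1", ch, U(1000, 3500), id)
      add_mark("p300", ch, U(1500, 3000), id)
      enh <- U(1500, 3000)
      t_truth$enh_start <- enh[1]; t_truth$enh_end <- enh[2]
    }
    if (cls == "eotr") {
      add_mark("h3k27ac", ch, U(1400, 3100), id)
      add_mark("h3k9ac", ch, U(1450, 3050), id)
      add_mark("h3k4me3", ch, U(300, 1300), id)
      add_mark("h3k36me3", ch, U(1400, 3250), id)
      tx <- U(1200, 3200)
      t_truth$tx_id <- id
      t_truth$tss <- if (st == "+") tx[1] else tx[2]
      t_truth$tts <- if (st == "+") tx[2] else tx[1]
      lg2 <- runif(1, cfg$eotr_cpm_range[1], cfg$eotr_cpm_range[2])
      t_truth$cpm_log2 <- lg2
      spliced <- runif(1) < 0.4
      exons <- if (spliced) rbind(U(1200, 2000), U(2400, 3200))
      else rbind(tx)
      gtf_cand[[id]] <- list(id = id, chrom = ch, strand = st,
                             exons = exons, polya = TRUE, cpm = 2^lg2)
      rna_mu[[id]] <- c(rep(2^lg2, 3), rep(0.1, 3))
      peak_u <- 1190
      pk <- U(peak_u, peak_u + 1)[1]
      cl <- U(1140, 1240)
      cage[[length(cage) + 1L]] <- data.frame(
        chrom = ch, start = cl[1], end = cl[2], name = paste0("cage_", id),
        idr = round(runif(1, 0.77, 1.0), 3), strand = st, peak = pk)
      # two TFBSs (100 bp) inside both the enhancer and the transcript
      for (k in 1:2) {
        se <- U(c(1800, 2300)[k], c(1800, 2300)[k] + 100)
        plant_tfbs(ch, se, sprintf("%s_tfbs%d", id, k),
                   c("TFA", "TFB")[k], id, gamma_occ, "occluded")
        add_gro(ch, se, r_f)
      }
      t_truth$gamma <- gamma_occ
      t_truth$pausing_ratio <- cfg$pausing_ratio
      # baseline polymerase signal over the domain outside the TSS peak
      # and the (already emitted) paused TFBS segments
      tssr <- U(1200, 1400)
      add_gro(ch, tssr, r_t)
      specials <- rbind(tssr, U(1800, 1900), U(2300, 2400))
      specials <- specials[order(specials[, 1]), , drop = FALSE]
      gap_lo <- c(tx[1], specials[, 2])
      gap_hi <- c(specials[, 1], tx[2])
      for (g in seq_along(gap_lo))
        if (gap_hi[g] > gap_lo[g])
          add_gro(ch, c(gap_lo[g], gap_hi[g]), r_b)
      h3k27ac_mu[[id]] <- 200 * cfg$h3k27ac_attenuation
      # allelic imbalance at every second EOTr locus
      if (i %% 2 == 0) {
        allele_loci <- c(allele_loci, id)
        t_truth$allelic <- TRUE
        for (sv in 1:4) {
          pos <- U(1200 + sv * 400, 1200 + sv * 400 + 1)[1]
          depth <- 50
          rc <- rbinom(1, depth, cfg$ase_imbalance)
          ase[[length(ase) + 1L]] <- data.frame(
            chrom = ch, pos = pos, ref = "A", alt = "G",
            ref_count = rc, alt_count = depth - rc, feature_id = id)
        }
      }
    } else if (cls == "erna") {
      add_mark("h3k27ac", ch, U(1400, 3100), id)
      add_mark("h3k9ac", ch, U(1450, 3050), id)
      tx <- U(1700, 2700)
      t_truth$tx_id <- id
      t_truth$tss <- if (st == "+") tx[1] else tx[2]
      t_truth$tts <- if (st == "+") tx[2] else tx[1]
      lg2 <- runif(1, cfg$erna_cpm_range[1], cfg$erna_cpm_range[2])
      t_truth$cpm_log2 <- lg2
      gtf_cand[[id]] <- list(id = id, chrom = ch, strand = st,
                             exons = rbind(tx), polya = FALSE,
                             cpm = 2^lg2)
      rna_mu[[id]] <- rep(2^lg2, 6)
      for (k in 1:2) {
        se <- U(c(1800, 2300)[k], c(1800, 2300)[k] + 100)
        plant_tfbs(ch, se, sprintf("%s_tfbs%d", id, k),
                   c("TFA", "TFB")[k], id, cfg$gamma_active, "control")
      }
      t_truth$gamma <- cfg$gamma_active
      t_truth$pausing_ratio <- 1
      add_gro(ch, tx, r_b)  # flat: no pausing at eRNA loci
      h3k27ac_mu[[id]] <- 250
    } else if (cls == "inert") {
      h3k27ac_mu[[id]] <- 200
      add_mark("ctcf", ch, U(4000, 4200), id)
    } else {
      # known gene hosting either an mRNA-like copy or an intron fragment
      gid <- sprintf("gene_%03d", i)
      # alternate activity on the slot index so both chromosomes carry
      # active and poised gene promoters (the loop planting needs every
      # chrom x activity combination)
      active <- (slot_idx[i] %% 2L == 0L)
      ppr <- U(0, 600)
      add_mark("h3k4me3", ch, ppr, gid)
      if (active) {
        add_mark("h3k4me2", ch, ppr, gid)
        add_mark("h3k27ac", ch, ppr, gid)
        add_mark("rnapii", ch, ppr, gid)
      } else {
        add_mark("h3k27me3", ch, ppr, gid)
      }
      add_mark("h3k36me3", ch, U(600, 3500), gid)
      if (cls == "mrna_like") {
        exons <- rbind(U(500, 1400), U(2600, 3500))
        orf <- paste0("ATG",
                      paste(sample(codons, 597, replace = TRUE),
                            collapse = ""), "TAA")
        plant(ch, exons[1, 1], substr(orf, 1, 900))
        plant(ch, exons[2, 1], substr(orf, 901, 1797))
        gtf_known[[gid]] <- list(id = gid, chrom = ch, strand = st,
                                 exons = exons, polya = TRUE, cpm = 0)
        gtf_cand[[id]] <- list(id = id, chrom = ch, strand = st,
                               exons = exons, polya = TRUE, cpm = 20)
        t_truth$tx_id <- id
        rna_mu[[id]] <- rep(20, 6)
      } else {
        exons <- rbind(U(500, 1100), U(2900, 3500))
        gtf_known[[gid]] <- list(id = gid, chrom = ch, strand = st,
                                 exons = exons, polya = TRUE, cpm = 0)
        frag <- U(1400, 2600)
        fst <- sample(c("+", "-"), 1)
        gtf_cand[[id]] <- list(id = id, chrom = ch, strand = fst,
                               exons = rbind(frag), polya = FALSE,
                               cpm = 2)
        t_truth$tx_id <- id
        t_truth$tss <- if (fst == "+") frag[1] else frag[2]
        rna_mu[[id]] <- rep(2, 6)
      }
      known_genes[[gid]] <- list(id = gid, chrom = ch, ppr = ppr,
                                 active = active)
    }
    truth[[i]] <- t_truth
  }
  truth <- do.call(rbind, truth)

  # loops: enhancer anchor <-> known-gene promoter anchor; the global
  # intra:inter ratio is planted at 5:2 by cycling the assignment
  kg <- do.call(rbind, lapply(known_genes, function(g)
    data.frame(id = g$id, chrom = g$chrom, start = g$ppr[1],
               end = g$ppr[2], active = g$active)))
  cycle <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)  # intra flags
  li <- 0L
  if (is.null(kg)) kg <- data.frame()
  for (i in if (nrow(kg)) which(truth$class %in% c("eotr", "erna"))
       else integer()) {
    cls <- truth$class[i]
    n_l <- if (cls == "eotr") cfg$loops_per_occluded_enhancer
    else cfg$loops_per_active_enhancer
    want_active <- cls == "erna"
    for (k in seq_len(n_l)) {
      li <- li + 1L
      intra <- cycle[(li - 1L) %% length(cycle) + 1L] ||
        cfg$n_chroms == 1L
      pool <- kg[kg$active == want_active &
                   ((kg$chrom == truth$chrom[i]) == intra), ,
                 drop = FALSE]
      if (nrow(pool) == 0L) pool <- kg
      g <- pool[sample.int(nrow(pool), 1L), ]
      loops[[length(loops) + 1L]] <- data.frame(
        chromA = truth$chrom[i], startA = truth$enh_start[i],
        endA = truth$enh_end[i], chromB = g$chrom, startB = g$start,
        endB = g$end, name = sprintf("%s_loop%d", truth$locus[i], k),
        score = 1)
      truth$n_loops[i] <- truth$n_loops[i] + 1L
    }
  }

  # ---- write files ----
  f <- function(...) file.path(out_dir, ...)
  dna <- Biostrings::DNAStringSet(vapply(genome, paste, "",
                                         collapse = ""))
  names(dna) <- chroms
  Biostrings::writeXStringSet(dna, f("genome.fa"), width = 80L)
  for (m in marks) {
    d <- mk[[m]]
    gr <- if (nrow(d)) intervals(d$chrom, d$start, d$end, name = d$name,
                                 score = 0) else GenomicRanges::GRanges()
    write_bed(gr, f("marks", paste0(m, ".bed")))
  }
  write_ts <- function(lst, path) {
    if (length(lst) == 0L) { writeLines(character(), path); return() }
    ex <- do.call(rbind, lapply(lst, function(t) {
      e <- t$exons
      data.frame(chrom = t$chrom, start = e[, 1], end = e[, 2],
                 strand = t$strand, id = t$id, polya = t$polya,
                 cpm = t$cpm)
    }))
    gr <- intervals(ex$chrom, ex$start, ex$end, strand = ex$strand)
    S4Vectors::mcols(gr)$transcript_id <- ex$id
    ts <- transcript_set_from_exons(gr, polya = as.character(ex$polya),
                                    cpm = ex$cpm)
    ts$tx$polyadenylated <- ex$polya[match(ts$tx$id, ex$id)]
    write_gtf_transcripts(ts, path)
  }
  write_ts(gtf_cand, f("transcripts.gtf"))
  write_ts(gtf_known, f("refseq.gtf"))
  cg <- do.call(rbind, cage)
  if (is.null(cg)) writeLines(character(), f("cage.bed")) else
    writeLines(paste(cg$chrom, cg$start, cg$end, cg$name, cg$idr,
                     cg$strand, cg$peak, sep = "\t"), f("cage.bed"))
  gd <- do.call(rbind, gro)
  if (!is.null(gd)) {
    gd <- gd[gd$value > 0, ]
    gd <- gd[order(gd$chrom, gd$start), ]
    writeLines(paste(gd$chrom, gd$start, gd$end, gd$value, sep = "\t"),
               f("groseq.bedgraph"))
  } else writeLines(character(), f("groseq.bedgraph"))
  tb <- do.call(rbind, tfbs)
  if (!is.null(tb))
    writeLines(paste(tb$chrom, tb$start, tb$end, tb$name, 0, ".", tb$tf,
                     sep = "\t"), f("tfbs.bed"))
  else writeLines(character(), f("tfbs.bed"))
  tfc <- do.call(rbind, tfc)
  if (!is.null(tfc))
    write.table(tfc, f("tf_counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  # RNA counts: NB around planted CPM (library size 1e6 => mu = CPM)
  ids <- names(rna_mu)
  cnt <- t(vapply(ids, function(id)
    .rnbinom2(6, rna_mu[[id]], cfg$nb_dispersion), numeric(6)))
  colnames(cnt) <- c(paste0("cellA_rep", 1:3), paste0("cellB_rep", 1:3))
  rownames(cnt) <- ids
  write_count_matrix(cnt, f("rna_counts.tsv"),
                     setNames(rep(1e6, 6), colnames(cnt)))
  # bulk H3K27ac counts per enhancer locus
  hids <- names(h3k27ac_mu)
  hc <- t(vapply(hids, function(id)
    .rnbinom2(3, h3k27ac_mu[[id]], cfg$nb_dispersion), numeric(3)))
  colnames(hc) <- paste0("rep", 1:3)
  rownames(hc) <- hids
  write_count_matrix(hc, f("h3k27ac_counts.tsv"))
  # allelic H3K27ac counts at allelic EOTr loci
  if (length(allele_loci)) {
    ac <- t(vapply(allele_loci, function(id) {
      c(.rnbinom2(3, 200 / cfg$allele_activity_fold, cfg$nb_dispersion),
        .rnbinom2(3, 200, cfg$nb_dispersion))
    }, numeric(6)))
    colnames(ac) <- c(paste0("eotr_rep", 1:3), paste0("other_rep", 1:3))
    rownames(ac) <- allele_loci
    write_count_matrix(ac, f("h3k27ac_allele_counts.tsv"))
  }
  av <- do.call(rbind, ase)
  if (!is.null(av))
    write.table(av, f("ase_counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  lp <- do.call(rbind, loops)
  if (!is.null(lp)) write_bedpe(lp, f("loops.bedpe"))
  else writeLines(character(), f("loops.bedpe"))
  write.table(truth, f("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(truth = truth, dir = out_dir,
                 files = list.files(out_dir, recursive = TRUE)))
}

#' Load a simulated dataset back into memory
#' @param dir directory written by [simulate_loci()].
#' @return list of parsed inputs (marks, transcripts, cage, tracks, ...).
#' @export
load_sim <- function(dir) {
  f <- function(...) file.path(dir, ...)
  marks <- c("h3k4me1", "h3k4me3", "h3k4me2", "h3k36me3", "h3k27ac",
             "h3k9ac", "h3k27me3", "p300", "rnapii", "ctcf")
  mk <- setNames(lapply(marks, function(m)
    read_bed(f("marks", paste0(m, ".bed")))), marks)
  tfbs <- read_bed(f("tfbs.bed"))
  if (length(tfbs))
    S4Vectors::mcols(tfbs)$tf <- S4Vectors::mcols(tfbs)$extra
  list(genome = read_fasta(f("genome.fa")), marks = mk,
       transcripts = read_gtf_transcripts(f("transcripts.gtf")),
       known_genes = read_gtf_transcripts(f("refseq.gtf")),
       cage = read_cage(f("cage.bed")),
       groseq = read_bedgraph(f("groseq.bedgraph")),
       tfbs = tfbs,
       tf_counts = read.table(f("tf_counts.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE),
       rna_counts = read_count_matrix(f("rna_counts.tsv")),
       h3k27ac_counts = read_count_matrix(f("h3k27ac_counts.tsv")),
       h3k27ac_allele_counts = if (file.exists(
         f("h3k27ac_allele_counts.tsv")))
         read_count_matrix(f("h3k27ac_allele_counts.tsv")) else NULL,
       ase = if (file.exists(f("ase_counts.tsv")))
         read.table(f("ase_counts.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE) else NULL,
       loops = read_bedpe(f("loops.bedpe")),
       truth = read.table(f("truth.tsv"), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE))
}

#' Join pipeline predictions to the planted truth
#'
#' @param predicted data.frame with columns `id` and `label`.
#' @param truth data.frame with columns `id` and `label` (every predicted
#'   id must appear).
#' @return data.frame with per-label `tp`, `fp`, `fn`, `precision`,
#'   `recall`.
#' @export
truth_join <- function(predicted, truth) {
  missing_ids <- setdiff(predicted$id, truth$id)
  if (length(missing_ids))
    stop("unmatched ids: ", paste(missing_ids, collapse = ", "))
  m <- merge(truth, predicted, by = "id", all.x = TRUE,
             suffixes = c("_true", "_pred"))
  labels <- union(unique(m$label_true), stats::na.omit(m$label_pred))
  do.call(rbind, lapply(labels, function(l) {
    tp <- sum(m$label_true == l & !is.na(m$label_pred) &
                m$label_pred == l)
    fp <- sum(m$label_true != l & !is.na(m$label_pred) &
                m$label_pred == l)
    fn <- sum(m$label_true == l & (is.na(m$label_pred) |
                                     m$label_pred != l))
    data.frame(label = l, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
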