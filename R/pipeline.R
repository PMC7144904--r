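# End-to-end orchestration over a simulated (or equivalently structured)
# dataset directory: states -> cascade -> affinity -> pausing -> ase ->
# loops -> differential, emitting the tabular reports.

#' Run the full analysis pipeline on a dataset directory
#'
#' Expects the file layout written by [simulate_loci()]. Stages run in
#' order; a failing stage halts with its name, retaining the reports
#' written so far. All randomness is governed by `seed`.
#'
#' @param dir dataset directory.
#' @param out_dir report output directory (default `file.path(dir,
#'   "reports")`).
#' @param seed integer seed for permutation-based stages.
#' @param idr_min,coding_cutoff,l2fc_threshold,alpha thresholds (defaults:
#'   0.77, 0.364, 1.5, 0.05).
#' @param run_affinity toggle the affinity stage; the final occlusion call
#'   depends on it, so disabling it is an error unless `finalize = FALSE`.
#' @param finalize produce the final EOTr calls (requires affinity).
#' @return invisibly, a list with every stage result and report paths.
#' @export
run_pipeline <- function(dir, out_dir = file.path(dir, "reports"),
                         seed = 1, idr_min = 0.77, coding_cutoff = 0.364,
                         l2fc_threshold = 1.5, alpha = 0.05,
                         run_affinity = TRUE, finalize = TRUE) {
  if (finalize && !run_affinity)
    stop("stage 'finalize_eotrs' requires the affinity stage: ",
         "enable run_affinity or set finalize = FALSE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  d <- stage("load", load_sim(dir))
  res <- list()

  res$enhancers <- stage("states", classify_enhancers(
    d$marks$h3k4me1, d$marks$p300, d$marks$h3k27ac, d$marks$h3k9ac))
  res$promoters <- stage("states", classify_promoters(
    d$marks$h3k4me3, d$marks$h3k4me2, d$marks$h3k27ac, d$marks$rnapii,
    d$marks$h3k27me3))
  res$erna <- stage("states", identify_erna_domains(
    d$marks$h3k4me1, d$marks$h3k27ac, d$marks$h3k9ac, d$marks$p300,
    d$marks$h3k36me3, d$marks$h3k4me3, transcripts = d$transcripts,
    cage = d$cage))

  # affinity per TF over its TFBS regions
  pwm <- sim_pwm()
  affinity_calls <- NULL
  if (run_affinity) {
    affinity_calls <- stage("affinity", {
      do.call(rbind, lapply(split(d$tf_counts,
                                  paste(d$tf_counts$tf,
                                        d$tf_counts$class)), function(g) {
        seqs <- vapply(seq_len(nrow(g)), function(i)
          as.character(Biostrings::subseq(d$genome[[g$chrom[i]]],
                                          g$start[i] + 1, g$end[i])), "")
        fit <- stap_fit(seqs, g$count, pwm)
        data.frame(tf = g$tf[1], group = g$class[1],
                   gamma = fit$gamma, exp_ratios = fit$exp_ratios,
                   max_binding_wts = fit$max_binding_wts,
                   call = fit$call, stringsAsFactors = FALSE)
      }))
    })
    res$affinity <- affinity_calls
  }

  # cascade (CP model trained on the dataset's own coding vs noncoding
  # transcript classes)
  res$cascade <- stage("cascade", {
    seqs_of <- function(ids) vapply(ids, function(id)
      transcript_sequence(d$transcripts, id, d$genome), "")
    tr <- d$truth
    coding_ids <- tr$tx_id[tr$class == "mrna_like" & !is.na(tr$tx_id)]
    noncod_ids <- tr$tx_id[tr$class %in% c("erna", "intron_fragment") &
                             !is.na(tr$tx_id)]
    model <- train_cp(seqs_of(coding_ids), seqs_of(noncod_ids))
    per_tfbs <- NULL
    if (run_affinity) {
      # a TFBS inherits its TF+group fit; cascade keys on TFBS ids
      key <- paste(d$tf_counts$tf, d$tf_counts$class)
      fitkey <- paste(affinity_calls$tf, affinity_calls$group)
      per_tfbs <- data.frame(
        tfbs_id = d$tf_counts$tfbs_id,
        call = affinity_calls$call[match(key, fitkey)],
        stringsAsFactors = FALSE)
    }
    run_cascade(d$transcripts, d$known_genes, d$genome, model,
                d$marks$h3k36me3, d$marks$h3k4me3, res$enhancers,
                d$cage, d$tfbs, per_tfbs, idr_min = idr_min,
                coding_cutoff = coding_cutoff)
  })

  # pausing over occluded TFBSs within their transcribed domains
  res$pausing <- stage("pausing", {
    # every TFBS inside a transcribed domain: occluded (EOTr) sites show
    # the planted pausing, control (eRNA) sites a flat profile, and the
    # across-class correlation with ChIP signal is the occlusion signature
    occ <- d$tf_counts
    tr <- d$truth[match(occ$locus, d$truth$locus), ]
    tx <- d$transcripts$tx[match(tr$tx_id, d$transcripts$tx$id), ]
    keep <- !is.na(tx$id)
    occ <- occ[keep, , drop = FALSE]; tx <- tx[keep, , drop = FALSE]
    if (nrow(occ) == 0L) NULL else
      do.call(rbind, lapply(seq_len(nrow(occ)), function(i) {
        pi <- pausing_index(d$groseq,
                            intervals(occ$chrom[i], occ$start[i],
                                      occ$end[i]),
                            intervals(tx$chrom[i], tx$start[i],
                                      tx$end[i]))
        data.frame(tfbs_id = occ$tfbs_id[i], locus = occ$locus[i],
                   class = occ$class[i],
                   pausing_index = pi$pausing_index,
                   feature_mean = pi$feature_mean,
                   domain_mean = pi$domain_mean, chip = occ$count[i])
      }))
  })

  res$ase <- stage("ase", {
    if (is.null(d$ase)) NULL else do.call(rbind, lapply(
      seq_len(nrow(d$ase)), function(i) {
        a <- ase_test(d$ase$ref_count[i], d$ase$alt_count[i])
        data.frame(chrom = d$ase$chrom[i], pos = d$ase$pos[i],
                   feature_id = d$ase$feature_id[i],
                   p_binom = a$p_binom, significant = a$significant,
                   allele = a$allele_with_eotr)
      }))
  })

  res$loops <- stage("loops", assign_loops(
    d$loops, res$enhancers, d$marks$h3k4me3, d$marks$ctcf,
    promoter_states = res$promoters))
  res$contact <- contact_ratio(res$loops)

  res$differential <- stage("differential", {
    cnt <- d$rna_counts$counts
    differential_call(cnt[, 1:3, drop = FALSE],
                      cnt[, 4:6, drop = FALSE],
                      l2fc_threshold = l2fc_threshold, alpha = alpha,
                      seed = seed,
                      library_sizes = d$rna_counts$library_sizes)
  })

  # final EOTr table keyed to truth for recovery checks
  if (finalize) {
    rec <- res$cascade$records
    res$eotr_calls <- data.frame(
      id = d$truth$tx_id[!is.na(d$truth$tx_id)],
      stringsAsFactors = FALSE)
    res$eotr_calls$is_eotr <- res$eotr_calls$id %in%
      rec$id[rec$is_eotr]
  }

  # reports
  wt <- function(x, name) {
    if (is.null(x)) return(NULL)
    x <- as.data.frame(lapply(x, function(col)
      if (is.list(col)) vapply(col, paste, "", collapse = ",") else col))
    p <- file.path(out_dir, name)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  res$reports <- c(
    wt(res$cascade$report, "cascade_table.tsv"),
    wt(data.frame(comparison = c("tts_upstream_flank",
                                 "tts_downstream_flank"),
                  jaccard = c(res$cascade$jaccard_up,
                              res$cascade$jaccard_down)),
       "jaccard_table.tsv"),
    wt(res$affinity, "affinity_table.tsv"),
    wt(res$pausing, "pausing_table.tsv"),
    wt(res$ase, "ase_table.tsv"),
    wt(res$loops, "loop_table.tsv"),
    wt(res$differential, "differential_table.tsv"))
  # machine-readable run summary
  summ <- c(
    sprintf('"stage_%s": %d', res$cascade$report$stage,
            res$cascade$report$total),
    sprintf('"n_eotr": %d', sum(res$cascade$records$is_eotr)),
    sprintf('"contact_ratio": %s',
            if (is.finite(res$contact$ratio))
              format(res$contact$ratio) else '"Inf"'),
    sprintf('"seed": %d', as.integer(seed)))
  writeLines(paste0("{", paste(summ, collapse = ", "), "}"),
             file.path(out_dir, "summary.json"))
  invisible(res)
}
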