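#' Preprocess one ROI run for MVCS analysis
#'
#' Applies the fixed pre-MVCS pipeline: detrend + discrete-cosine
#' high-pass filter, optional down-sampling to a slower target TR (when
#' the run will be paired with a slower-TR run), framewise-displacement
#' scrubbing (exceeding volumes plus their successors), gray-matter voxel
#' selection, and nuisance regression (24 expanded motion regressors plus
#' the first principal components of the WM and CSF pools, rows censored
#' with the same frame mask as the data).
#'
#' @param run a [roi_ts()] object.
#' @param motion the run's [motion_params()] table.
#' @param wm_pool,csf_pool optional tissue signal pools (time x signal).
#' @param gm_prob optional per-voxel gray-matter probabilities.
#' @param target_tr optional slower TR to down-sample to before scrubbing.
#' @param fd_threshold_mm scrubbing threshold (default 0.5 mm).
#' @param highpass_hz high-pass cutoff (default 1/128 Hz).
#' @param gm_threshold gray-matter inclusion threshold (default 0.10).
#' @param n_tissue_pcs principal components per tissue (default 3).
#' @return the cleaned [roi_ts()]; attributes `n_input_volumes`,
#'   `n_censored`, `censored_fraction` document the scrubbing.
#' @export
preprocess_run <- function(run, motion, wm_pool = NULL, csf_pool = NULL,
                           gm_prob = NULL, target_tr = NULL,
                           fd_threshold_mm = 0.5, highpass_hz = 1 / 128,
                           gm_threshold = 0.10, n_tissue_pcs = 3) {
  stopifnot(inherits(run, "roi_ts"))
  motion <- motion_params(motion)
  if (nrow(motion) != nrow(run$data))
    stop_mvcsi("mvcsi_invalid",
               "motion rows (%d) do not match run volumes (%d)",
               nrow(motion), nrow(run$data))
  out <- detrend_highpass(run, highpass_hz)
  if (!is.null(target_tr) && target_tr > run$tr) {
    out <- resample_to_tr(out, target_tr)
    motion <- motion_params(resample_matrix(unclass(motion), run$tr,
                                            target_tr))
    if (!is.null(wm_pool))
      wm_pool <- resample_matrix(as.matrix(wm_pool), run$tr, target_tr)
    if (!is.null(csf_pool))
      csf_pool <- resample_matrix(as.matrix(csf_pool), run$tr, target_tr)
  }
  n_input <- nrow(out$data)
  fd <- compute_fd(motion)
  out <- censor_frames(out, fd, threshold_mm = fd_threshold_mm)
  keep <- out$frame_index  # rows on the (possibly resampled) grid
  censored_fraction <- attr(out, "censored_fraction")
  nuis <- build_motion_regressors(motion)[keep, , drop = FALSE]
  if (!is.null(wm_pool) && !is.null(csf_pool)) {
    tissue <- extract_tissue_components(
      as.matrix(wm_pool)[keep, , drop = FALSE],
      as.matrix(csf_pool)[keep, , drop = FALSE], k = n_tissue_pcs)
    nuis <- cbind(tissue, nuis)
  }
  if (!is.null(gm_prob))
    out <- select_voxels_gm(out, gm_prob, threshold = gm_threshold)
  out <- suppressMessages(regress_nuisance(out, nuis))
  attr(out, "n_input_volumes") <- n_input
  attr(out, "n_censored") <- n_input - nrow(out$data)
  attr(out, "censored_fraction") <- censored_fraction
  out
}

#' Pipeline configuration
#'
#' @param synthetic a [synth_config()] describing the study to generate,
#'   or `NULL` when `path` points at an on-disk study (see
#'   [write_study()]).
#' @param path optional directory of a written study.
#' @param fd_threshold_mm,highpass_hz,gm_threshold,n_tissue_pcs
#'   preprocessing thresholds, defaults as in [preprocess_run()].
#' @param min_volumes minimum matched pair length (default 30).
#' @param fit_behavior fit the block-level behavioral mixed models
#'   (default TRUE; the Kronecker fit is the slow step).
#' @param fdr_q FDR level across ROIs (default 0.05).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synth_config(), path = NULL,
                            fd_threshold_mm = 0.5, highpass_hz = 1 / 128,
                            gm_threshold = 0.10, n_tissue_pcs = 3,
                            min_volumes = 30, fit_behavior = TRUE,
                            fdr_q = 0.05) {
  for (v in c(fd_threshold_mm, highpass_hz, gm_threshold, n_tissue_pcs,
              min_volumes))
    if (!is.numeric(v) || v < 0)
      stop_mvcsi("mvcsi_invalid", "thresholds must be non-negative")
  if (!is.null(path) && !dir.exists(path))
    stop_mvcsi("mvcsi_invalid", "study path does not exist: %s", path)
  structure(list(synthetic = synthetic, path = path,
                 fd_threshold_mm = fd_threshold_mm,
                 highpass_hz = highpass_hz, gm_threshold = gm_threshold,
                 n_tissue_pcs = n_tissue_pcs, min_volumes = min_volumes,
                 fit_behavior = fit_behavior, fdr_q = fdr_q),
            class = "pipeline_config")
}

#' Run the full MVCS similarity pipeline
#'
#' Generates (or loads) a study, preprocesses every run, computes the
#' similarity index for the three run pairings per subject, condition and
#' ROI, derives block-level task performance, fits the repeated-measures
#' mixed models per ROI and pairing (plus the behavioral models), applies
#' Benjamini-Hochberg FDR across ROIs within each pairing and effect, and
#' computes the standard follow-up condition contrasts. Deterministic
#' given the configuration (including its seed).
#'
#' @param config a [pipeline_config()].
#' @return object of class `study_report`: list with `si_table`,
#'   `lmm_table`, `followups`, `behavior_blocks`, `behavior_lmm`,
#'   `exclusions`, `omitted` (unusable pairs with reasons) and
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- if (!is.null(config$path)) read_study(config$path)
    else generate_experiment(config$synthetic)
  cfg <- study$config
  si_rows <- list(); excl_rows <- list(); omitted <- list()
  beh_rows <- list()
  for (s in names(study$sessions)) {
    for (cond in names(study$sessions[[s]])) {
      ses <- study$sessions[[s]][[cond]]
      meta0 <- list(subject = s, visit = ses$visit,
                    stimulation = if (substr(cond, 1, 1) == "c") "cTBS"
                      else "iTBS",
                    task = substr(cond, 2, 4), condition = cond)
      bp <- block_performance(ses$keypresses)
      beh_rows[[paste(s, cond)]] <-
        cbind(as.data.frame(meta0, stringsAsFactors = FALSE)[
          rep(1, nrow(bp)), , drop = FALSE], bp)
      for (roi in names(ses$rois)) {
        rr <- ses$rois[[roi]]
        pp <- function(run, rn, target_tr = NULL) {
          if (is.null(run)) return(NULL)
          tryCatch(preprocess_run(
            run, ses$motion[[rn]], ses$wm_pool[[rn]], ses$csf_pool[[rn]],
            gm_prob = rr$gm_prob, target_tr = target_tr,
            fd_threshold_mm = config$fd_threshold_mm,
            highpass_hz = config$highpass_hz,
            gm_threshold = config$gm_threshold,
            n_tissue_pcs = config$n_tissue_pcs),
            mvcsi_error = function(e) {
              omitted[[paste(s, cond, roi, rn)]] <<- conditionMessage(e)
              NULL
            })
        }
        task_pp <- pp(rr$task, "task")
        pre_pp <- pp(rr$pre_rs, "pre_rs")
        post_pp <- pp(rr$post_rs, "post_rs")
        post_task_pp <- pp(rr$post_rs, "post_rs", target_tr = cfg$task_tr)
        for (rn in c("task", "pre_rs", "post_rs")) {
          run_pp <- switch(rn, task = task_pp, pre_rs = pre_pp,
                           post_rs = post_pp)
          if (!is.null(run_pp))
            excl_rows[[paste(s, cond, roi, rn)]] <- data.frame(
              subject = s, condition = cond, roi = roi, run = rn,
              n_input_volumes = attr(run_pp, "n_input_volumes"),
              n_censored = attr(run_pp, "n_censored"),
              n_retained = nrow(run_pp$data),
              censored_fraction = attr(run_pp, "censored_fraction"))
        }
        recs <- assemble_pairings(
          task = task_pp, pre_rs = pre_pp, post_rs = post_pp,
          post_rs_at_task_tr = post_task_pp,
          meta = c(meta0, list(roi = roi)),
          min_volumes = config$min_volumes)
        om <- attr(recs, "omitted")
        for (nm in names(om))
          omitted[[paste(s, cond, roi, nm)]] <- om[[nm]]
        if (nrow(recs)) si_rows[[paste(s, cond, roi)]] <- recs
      }
    }
  }
  si_table <- do.call(rbind, unname(si_rows))
  rownames(si_table) <- NULL
  behavior_blocks <- do.call(rbind, unname(beh_rows))
  rownames(behavior_blocks) <- NULL

  # per-ROI mixed models per pairing, FDR across ROIs within pairing x term
  lmm_rows <- list(); follow_rows <- list(); fits <- list()
  for (pairing in unique(si_table$pairing)) {
    for (roi in unique(si_table$roi)) {
      d <- si_table[si_table$pairing == pairing & si_table$roi == roi, ]
      if (length(unique(d$subject)) < 3) next
      fit <- tryCatch(fit_lmm_si(d), mvcsi_error = function(e) NULL)
      if (is.null(fit)) next
      fits[[paste(pairing, roi)]] <- fit
      tab <- fit$anova
      tab <- cbind(data.frame(roi = roi, pairing = pairing), tab)
      lmm_rows[[paste(pairing, roi)]] <- tab
      fu <- tryCatch(rbind(
        cbind(data.frame(contrast = "cSEQ-cRND"),
              followup_contrast(fit,
                                a = list(stimulation = "cTBS", task = "SEQ"),
                                b = list(stimulation = "cTBS",
                                         task = "RND"))),
        cbind(data.frame(contrast = "cSEQ-iSEQ"),
              followup_contrast(fit,
                                a = list(stimulation = "cTBS", task = "SEQ"),
                                b = list(stimulation = "iTBS",
                                         task = "SEQ")))),
        error = function(e) NULL)
      if (!is.null(fu))
        follow_rows[[paste(pairing, roi)]] <-
          cbind(data.frame(roi = roi, pairing = pairing), fu)
    }
  }
  lmm_table <- do.call(rbind, unname(lmm_rows))
  if (!is.null(lmm_table)) {
    rownames(lmm_table) <- NULL
    lmm_table$p_fdr <- NA_real_
    for (pairing in unique(lmm_table$pairing)) {
      for (term in unique(lmm_table$term)) {
        sel <- lmm_table$pairing == pairing & lmm_table$term == term &
          is.finite(lmm_table$p)
        if (any(sel))
          lmm_table$p_fdr[sel] <- p.adjust(lmm_table$p[sel], method = "BH")
      }
    }
  }
  followups <- do.call(rbind, unname(follow_rows))
  if (!is.null(followups)) rownames(followups) <- NULL

  behavior_lmm <- NULL
  if (isTRUE(config$fit_behavior)) {
    behavior_lmm <- list(
      speed = tryCatch(fit_lmm_behavior(behavior_blocks,
                                        response = "mean_rt_correct"),
                       error = function(e) e),
      accuracy = tryCatch(fit_lmm_behavior(behavior_blocks,
                                           response = "accuracy"),
                          error = function(e) e))
  }
  exclusions <- do.call(rbind, unname(excl_rows))
  rownames(exclusions) <- NULL
  structure(list(
    si_table = si_table, lmm_table = lmm_table, followups = followups,
    si_fits = fits, behavior_blocks = behavior_blocks,
    behavior_lmm = behavior_lmm, exclusions = exclusions,
    omitted = omitted,
    provenance = list(config = config, seed = cfg$seed,
                      package_version =
                        as.character(utils::packageVersion("mvcsi")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("MVCS study report\n")
  cat(sprintf("  %d similarity records (%d subjects, %d ROIs, %d pairings)\n",
              nrow(x$si_table), length(unique(x$si_table$subject)),
              length(unique(x$si_table$roi)),
              length(unique(x$si_table$pairing))))
  cat(sprintf("  mean censored fraction: task %.2f%%, rest %.2f%%\n",
              100 * mean(x$exclusions$censored_fraction[
                x$exclusions$run == "task"]),
              100 * mean(x$exclusions$censored_fraction[
                x$exclusions$run != "task"])))
  if (length(x$omitted))
    cat(sprintf("  %d omitted run(s)/pair(s)\n", length(x$omitted)))
  if (!is.null(x$lmm_table)) {
    cat("Mixed-model effects (per ROI and pairing):\n")
    tab <- x$lmm_table
    tab$F <- round(tab$F, 3); tab$df2 <- round(tab$df2, 2)
    tab$p <- signif(tab$p, 3); tab$p_fdr <- signif(tab$p_fdr, 3)
    print(utils::head(tab[order(tab$pairing, tab$roi), ], 24),
          row.names = FALSE)
  }
  invisible(x)
}
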