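#' Generate a complete synthetic study
#'
#' Produces, for every subject and condition of the 2 x 2 stimulation-by-
#' task design, a pre-intervention resting run, a task run with block
#' annotations, a post-intervention resting run (per ROI), head-motion
#' tables, WM/CSF nuisance signal pools, gray-matter probabilities, a
#' key-press log, plus the design table and the ground-truth persistence
#' values that downstream recovery tests compare against. Pattern
#' persistence between run pairs is controlled per pairing and condition
#' (see [synth_config()]); the construction chains loading-matrix mixing so
#' that higher configured persistence yields higher expected similarity for
#' the corresponding pairing.
#'
#' @param config a [synth_config()] object.
#' @return an object of class `synth_study`: list with `config`, `design`,
#'   `ground_truth` and `sessions[[subject]][[condition]]`, each session
#'   holding `visit`, `rois[[roi]]` (`pre_rs`, `task`, `post_rs`
#'   [roi_ts()] runs and `gm_prob`), `motion`, `wm_pool`, `csf_pool`
#'   (per-run lists), and `keypresses`.
#' @export
generate_experiment <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  validate_synth_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    design <- study_design(cfg$n_subjects)
    sessions <- list()
    gt <- list()
    subj_sd <- if (is.null(cfg$behavior$subject_sd_ms)) 0
      else cfg$behavior$subject_sd_ms
    for (s in unique(design$subject)) {
      sessions[[s]] <- list()
      # stable per-subject baseline speed, shared across the four sessions
      rt_offset <- rnorm(1, 0, subj_sd)
      for (cond in condition_levels) {
        row <- design[design$subject == s & design$condition == cond, ]
        task_type <- row$task
        keypresses <- generate_behavior(
          task = task_type, n_blocks = cfg$n_blocks,
          presses_per_block = cfg$presses_per_block,
          baseline_rt_ms = cfg$behavior$baseline_rt_ms + rt_offset,
          learning_amp_ms = cfg$behavior$learning_amp_ms,
          learning_rate = cfg$behavior$learning_rate,
          accuracy = cfg$behavior$accuracy,
          rt_log_sd = cfg$behavior$rt_log_sd)
        sched <- task_schedule(keypresses, cfg$task_tr, cfg$rest_block_s)
        n_task <- sched$n_volumes
        vols <- c(pre_rs = cfg$rest_volumes, task = n_task,
                  post_rs = cfg$rest_volumes)
        trs <- c(pre_rs = cfg$rest_tr, task = cfg$task_tr,
                 post_rs = cfg$rest_tr)
        motion <- list(); wm <- list(); csf <- list(); latents <- list()
        artifacts <- list()
        for (rn in names(vols)) {
          motion[[rn]] <- generate_motion(vols[[rn]],
                                          spike_prob = cfg$spike_prob,
                                          spike_mag = cfg$spike_mag,
                                          walk_sd = cfg$walk_sd,
                                          walk_sd_rot = cfg$walk_sd_rot)
          latents[[rn]] <- vapply(seq_len(cfg$n_nuisance), function(j)
            smooth_signal(vols[[rn]], trs[[rn]]), numeric(vols[[rn]]))
          mix_wm <- matrix(rnorm(cfg$n_nuisance * cfg$pool_size),
                           cfg$n_nuisance)
          mix_csf <- matrix(rnorm(cfg$n_nuisance * cfg$pool_size),
                            cfg$n_nuisance)
          wm[[rn]] <- latents[[rn]] %*% mix_wm +
            matrix(rnorm(vols[[rn]] * cfg$pool_size, sd = 0.3),
                   vols[[rn]], cfg$pool_size)
          csf[[rn]] <- latents[[rn]] %*% mix_csf +
            matrix(rnorm(vols[[rn]] * cfg$pool_size, sd = 0.3),
                   vols[[rn]], cfg$pool_size)
          artifacts[[rn]] <- which(compute_fd(motion[[rn]]) > 0.5)
        }
        rois <- list()
        for (roi in names(cfg$rois)) {
          nv <- cfg$rois[[roi]]
          rho_el <- condition_rho(cfg, "early_late", cond)
          rho_pp <- condition_rho(cfg, "rs_pre_post", cond)
          rho_tp <- condition_rho(cfg, "task_rs_post", cond)
          w_pre <- random_loadings(nv, cfg$n_factors)
          w_early <- mix_loadings(w_pre, cfg$rho_task_anchor)
          w_late <- mix_loadings(w_early, rho_el)
          w_task_mean <- unit_cols(w_early + w_late)
          w_post <- unit_cols(
            sqrt(rho_pp) * w_pre + sqrt(rho_tp) * w_task_mean +
              sqrt(max(1 - rho_pp - rho_tp, 0.05)) *
              random_loadings(nv, cfg$n_factors))
          gm_prob <- runif(nv, 0.3, 1)
          low <- which(runif(nv) < cfg$gm_low_frac)
          gm_prob[low] <- runif(length(low), 0, 0.09)
          gen <- function(w, rn, switch_vols = integer(0)) {
            generate_roi_run(
              w, n_volumes = vols[[rn]], tr = trs[[rn]],
              signal_sd = cfg$signal_sd, noise_sd = cfg$noise_sd,
              drift_amplitude = cfg$drift_amplitude,
              nuisance_latent = latents[[rn]],
              nuisance_gamma = matrix(rnorm(nv * cfg$n_nuisance,
                                            sd = cfg$nuisance_sd),
                                      nv, cfg$n_nuisance),
              artifact_vols = artifacts[[rn]],
              artifact_sd = cfg$artifact_sd,
              switch_vols = switch_vols,
              voxel_ids = paste0(roi, "_v", seq_len(nv)))
          }
          late_start <- sched$annotations$start_vol[
            sched$annotations$block == cfg$n_blocks / 2 + 1 &
              sched$annotations$phase == "practice"]
          task_run <- gen(list(w_early, w_late), "task",
                          switch_vols = late_start)
          task_run$block_annotations <- sched$annotations
          rois[[roi]] <- list(pre_rs = gen(w_pre, "pre_rs"),
                              task = task_run,
                              post_rs = gen(w_post, "post_rs"),
                              gm_prob = gm_prob)
          gt[[length(gt) + 1L]] <- data.frame(
            subject = s, condition = cond, roi = roi,
            pairing = c("early_late", "rs_pre_post", "task_rs_post"),
            rho = c(rho_el, rho_pp, rho_tp))
        }
        sessions[[s]][[cond]] <- list(visit = row$visit, rois = rois,
                                      motion = motion, wm_pool = wm,
                                      csf_pool = csf,
                                      keypresses = keypresses)
      }
    }
    structure(list(config = cfg, design = design,
                   ground_truth = do.call(rbind, gt),
                   sessions = sessions),
              class = "synth_study")
  })
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d subjects x 4 conditions, ROIs [%s]\n",
              x$config$n_subjects, paste(names(x$config$rois),
                                         collapse = ", ")))
  invisible(x)
}

#' Simulate a similarity-index table directly
#'
#' Draws long-format similarity-index observations from the condition-cell
#' model the voxel-level generator targets, without simulating voxel data:
#' each subject contributes one SI value per condition, composed of a grand
#' mean, a subject random effect, additive condition effects expressed in
#' units of the within-cell standard deviation, and residual noise. This is
#' the fast path for mixed-model calibration and power studies where
#' thousands of replicate studies are needed.
#'
#' With effect coding `t, s = +/- 1/2` (SEQ/iTBS positive), an `effects`
#' entry of `d` shifts the corresponding marginal mean difference by
#' `d * sd_within`, where `sd_within = sqrt(subject_sd^2 + resid_sd^2)` is
#' the SD of SI values within one condition cell.
#'
#' @param n_subjects subjects (default 19).
#' @param effects named vector `task`, `stimulation`, `interaction` in
#'   within-cell SD units.
#' @param mu grand mean SI.
#' @param subject_sd,resid_sd between-subject and residual SDs.
#' @param missing_cells optional data frame (`subject`, `condition`) of
#'   cells to drop, emulating incomplete datasets.
#' @param seed optional seed.
#' @return data frame with columns `subject`, `visit`, `stimulation`,
#'   `task`, `condition`, `si`.
#' @export
simulate_si_study <- function(n_subjects = 19,
                              effects = c(task = 0, stimulation = 0,
                                          interaction = 0),
                              mu = 0.3, subject_sd = 0.10, resid_sd = 0.07,
                              missing_cells = NULL, seed = NULL) {
  with_seed(seed, {
    d <- study_design(n_subjects)
    sd_w <- sqrt(subject_sd^2 + resid_sd^2)
    t_c <- ifelse(d$task == "SEQ", 0.5, -0.5)
    s_c <- ifelse(d$stimulation == "iTBS", 0.5, -0.5)
    b_s <- rnorm(n_subjects, sd = subject_sd)
    names(b_s) <- unique(d$subject)
    d$si <- mu + b_s[d$subject] +
      sd_w * (effects[["task"]] * t_c + effects[["stimulation"]] * s_c +
                effects[["interaction"]] * t_c * s_c) +
      rnorm(nrow(d), sd = resid_sd)
    if (!is.null(missing_cells)) {
      drop <- paste(d$subject, d$condition) %in%
        paste(missing_cells$subject, missing_cells$condition)
      d <- d[!drop, , drop = FALSE]
    }
    rownames(d) <- NULL
    d
  })
}
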