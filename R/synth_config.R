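#' Configuration for the synthetic-study generator
#'
#' Collects every tunable of [generate_experiment()] with defaults that
#' emulate the study design the package targets: 19 subjects, a 2 x 2
#' within-subject crossing of stimulation (cTBS/iTBS) by task (SEQ/RND)
#' with Latin-square visit order over four sessions, two resting runs of
#' 300 volumes at TR 1 s flanking one task run at TR 2 s whose length
#' follows from 16 practice blocks of 48 key presses interleaved with 15 s
#' rest blocks, and ROIs of a few hundred voxels with low-rank latent
#' pattern structure.
#'
#' Pattern persistence between run pairs is controlled by `rho` (one value
#' in `[0, 1]` per pairing type) and modulated additively per condition by
#' `si_effects` on the persistence scale: with effect coding `t = +1/2` for
#' SEQ (`-1/2` for RND) and `s = +1/2` for iTBS (`-1/2` for cTBS), a
#' condition's persistence is
#' `rho + task * t + stimulation * s + interaction * t * s`, clipped to
#' `[0, 1]`.
#'
#' @param n_subjects number of subjects (default 19).
#' @param rois named integer vector: voxels per ROI (default a 250-voxel
#'   stimulation-target sphere and a 320-voxel subcortical ROI).
#' @param n_factors latent pattern factors per ROI (default 12).
#' @param rest_volumes,rest_tr resting-run length (300) and TR (1 s).
#' @param task_tr task-run TR (2 s).
#' @param n_blocks,presses_per_block task schedule (16 blocks of 48).
#' @param rest_block_s rest period between practice blocks (15 s).
#' @param rho named list/vector of baseline persistence per pairing
#'   (`early_late`, `rs_pre_post`, `task_rs_post`).
#' @param rho_task_anchor structural correlation between pre-rest and task
#'   patterns (not a measured pairing; default 0.35).
#' @param si_effects named vector `task`, `stimulation`, `interaction` of
#'   additive condition effects on persistence (default all 0).
#' @param signal_sd,noise_sd per-voxel latent signal and white-noise SD.
#' @param drift_amplitude amplitude of slow (below 1/128 Hz) drift terms.
#' @param n_nuisance,nuisance_sd,pool_size latent nuisance signals shared
#'   with the WM/CSF pools, their per-voxel coupling SD, and pool width.
#' @param spike_prob,spike_mag,walk_sd,walk_sd_rot motion controls: per-
#'   volume probability and size (mm) of sustained head-position steps, and
#'   the slow random-walk step SDs (mm translations, rad rotations).
#' @param artifact_sd amplitude of the signal glitch added on motion-spike
#'   volumes (in units of `noise_sd`).
#' @param gm_low_frac fraction of ROI voxels given gray-matter probability
#'   below the 10 % inclusion threshold.
#' @param behavior list of key-press parameters: `baseline_rt_ms` (A),
#'   `learning_amp_ms` (B), `learning_rate` (lambda, per block),
#'   `accuracy` (probability correct), `rt_log_sd` (log-normal RT spread),
#'   `subject_sd_ms` (SD of the per-subject baseline-speed offset shared
#'   across that subject's sessions). SEQ block means follow
#'   `A + B * exp(-lambda * (block - 1))`; RND block means are flat at
#'   `A + B`.
#' @param seed integer seed; fully determines the generated study.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 19,
                         rois = c(dlpfc = 250, hippocampus = 320),
                         n_factors = 12,
                         rest_volumes = 300, rest_tr = 1, task_tr = 2,
                         n_blocks = 16, presses_per_block = 48,
                         rest_block_s = 15,
                         rho = c(early_late = 0.7, rs_pre_post = 0.55,
                                 task_rs_post = 0.45),
                         rho_task_anchor = 0.35,
                         si_effects = c(task = 0, stimulation = 0,
                                        interaction = 0),
                         signal_sd = 1, noise_sd = 0.8,
                         drift_amplitude = 1.5,
                         n_nuisance = 4, nuisance_sd = 0.5, pool_size = 20,
                         spike_prob = 0.02, spike_mag = 0.8,
                         walk_sd = 0.01, walk_sd_rot = 2e-4,
                         artifact_sd = 3,
                         gm_low_frac = 0.1,
                         behavior = list(baseline_rt_ms = 500,
                                         learning_amp_ms = 150,
                                         learning_rate = 0.35,
                                         accuracy = 0.97,
                                         rt_log_sd = 0.25,
                                         subject_sd_ms = 40),
                         seed = 1L) {
  cfg <- list(n_subjects = n_subjects, rois = rois, n_factors = n_factors,
              rest_volumes = rest_volumes, rest_tr = rest_tr,
              task_tr = task_tr, n_blocks = n_blocks,
              presses_per_block = presses_per_block,
              rest_block_s = rest_block_s,
              rho = unlist(rho), rho_task_anchor = rho_task_anchor,
              si_effects = unlist(si_effects),
              signal_sd = signal_sd, noise_sd = noise_sd,
              drift_amplitude = drift_amplitude,
              n_nuisance = n_nuisance, nuisance_sd = nuisance_sd,
              pool_size = pool_size,
              spike_prob = spike_prob, spike_mag = spike_mag,
              walk_sd = walk_sd, walk_sd_rot = walk_sd_rot,
              artifact_sd = artifact_sd, gm_low_frac = gm_low_frac,
              behavior = behavior, seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  chk_count <- function(x, nm, min = 1) {
    if (!is.numeric(x) || any(x < min) || any(x != floor(x)))
      stop_mvcsi("mvcsi_invalid",
                 "field '%s' must be integer(s) >= %g, got %s", nm, min,
                 paste(x, collapse = ","))
  }
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop_mvcsi("mvcsi_invalid", "field '%s' must be a positive number", nm)
  }
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1))
      stop_mvcsi("mvcsi_invalid", "field '%s' must lie in [0, 1]", nm)
  }
  chk_count(cfg$n_subjects, "n_subjects")
  chk_count(cfg$rois, "rois", min = 10)
  if (is.null(names(cfg$rois)) || anyDuplicated(names(cfg$rois)))
    stop_mvcsi("mvcsi_invalid", "field 'rois' must have unique names")
  chk_count(cfg$n_factors, "n_factors")
  chk_count(cfg$rest_volumes, "rest_volumes", min = 8)
  chk_pos(cfg$rest_tr, "rest_tr"); chk_pos(cfg$task_tr, "task_tr")
  chk_count(cfg$n_blocks, "n_blocks", min = 2)
  chk_count(cfg$presses_per_block, "presses_per_block")
  need <- c("early_late", "rs_pre_post", "task_rs_post")
  if (!all(need %in% names(cfg$rho)))
    stop_mvcsi("mvcsi_invalid", "field 'rho' must name %s",
               paste(need, collapse = ", "))
  chk_prob(cfg$rho, "rho")
  chk_prob(cfg$rho_task_anchor, "rho_task_anchor")
  if (!all(c("task", "stimulation", "interaction") %in%
           names(cfg$si_effects)))
    stop_mvcsi("mvcsi_invalid",
               "field 'si_effects' must name task, stimulation, interaction")
  chk_prob(cfg$spike_prob, "spike_prob")
  chk_prob(cfg$gm_low_frac, "gm_low_frac")
  for (nm in c("signal_sd", "noise_sd"))
    if (cfg[[nm]] < 0) stop_mvcsi("mvcsi_invalid",
                                  "field '%s' must be >= 0", nm)
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    stop_mvcsi("mvcsi_invalid", "field 'seed' must be a single integer")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study config: %d subjects, ROIs [%s], ",
                     "rest %d vols @ %g s, task TR %g s, seed %d\n"),
              x$n_subjects,
              paste(sprintf("%s=%d", names(x$rois), x$rois), collapse = ", "),
              x$rest_volumes, x$rest_tr, x$task_tr, x$seed))
  cat(sprintf("  persistence: %s; effects: %s\n",
              paste(sprintf("%s=%.2f", names(x$rho), x$rho), collapse = ", "),
              paste(sprintf("%s=%.2f", names(x$si_effects), x$si_effects),
                    collapse = ", ")))
  invisible(x)
}

# Latin-square (cyclic, wrapping) visit order of the four conditions.
condition_levels <- c("cSEQ", "cRND", "iSEQ", "iRND")

#' Study design table with counterbalanced visit order
#'
#' One row per subject x condition with visit positions assigned by a
#' cyclic Latin square over the four conditions (wrapping over subjects),
#' so that with `n_subjects` divisible by 4 each condition occupies each
#' visit position equally often.
#'
#' @param n_subjects number of subjects.
#' @return data frame with columns `subject`, `visit` (1-4), `stimulation`
#'   (`cTBS`/`iTBS`), `task` (`SEQ`/`RND`), `condition`.
#' @export
study_design <- function(n_subjects) {
  subj <- sprintf("s%02d", seq_len(n_subjects))
  rows <- lapply(seq_len(n_subjects), function(s) {
    order <- condition_levels[((s - 1 + 0:3) %% 4) + 1]
    data.frame(subject = subj[s], visit = 1:4, condition = order,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d$stimulation <- ifelse(substr(d$condition, 1, 1) == "c", "cTBS", "iTBS")
  d$task <- substr(d$condition, 2, 4)
  d[, c("subject", "visit", "stimulation", "task", "condition")]
}

# Effect-coded persistence for one condition and pairing.
condition_rho <- function(cfg, pairing, condition) {
  t <- if (substr(condition, 2, 4) == "SEQ") 0.5 else -0.5
  s <- if (substr(condition, 1, 1) == "i") 0.5 else -0.5
  e <- cfg$si_effects
  min(1, max(0, cfg$rho[[pairing]] + e[["task"]] * t +
               e[["stimulation"]] * s + e[["interaction"]] * t * s))
}
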