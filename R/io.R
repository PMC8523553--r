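# Plain-text study serialisation: one directory per study with a design
# table, a config/ground-truth pair, and per subject x condition TSV files
# for every run, motion table, nuisance pool and key-press log.

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) read.delim(path, check.names = FALSE)

#' Write a synthetic study to a directory of TSV/JSON files
#'
#' Layout: `design.tsv`, `config.json`, `ground_truth.tsv`, and per
#' subject x condition a subdirectory `<subject>_<condition>/` holding
#' `keypresses.tsv`, and per run (`pre_rs`, `task`, `post_rs`)
#' `motion_<run>.tsv` (6 canonical columns), `wm_<run>.tsv`,
#' `csf_<run>.tsv`, plus per ROI `roi_<roi>_<run>.tsv` (volumes x voxels,
#' a header line `#tr <seconds>` first), `gm_<roi>.tsv`, and
#' `annotations_task.tsv`.
#'
#' @param study a [generate_experiment()] result.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synth_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(study$design, file.path(dir, "design.tsv"))
  write_tsv(study$ground_truth, file.path(dir, "ground_truth.tsv"))
  cfg <- unclass(study$config)
  # named vectors must go out as JSON objects, not bare arrays
  for (nm in c("rois", "rho", "si_effects")) cfg[[nm]] <- as.list(cfg[[nm]])
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in names(study$sessions)) {
    for (cond in names(study$sessions[[s]])) {
      ses <- study$sessions[[s]][[cond]]
      sd <- file.path(dir, paste0(s, "_", cond))
      dir.create(sd, showWarnings = FALSE)
      write_tsv(ses$keypresses, file.path(sd, "keypresses.tsv"))
      for (rn in names(ses$motion)) {
        write_tsv(as.data.frame(unclass(ses$motion[[rn]])),
                  file.path(sd, paste0("motion_", rn, ".tsv")))
        write_tsv(as.data.frame(ses$wm_pool[[rn]]),
                  file.path(sd, paste0("wm_", rn, ".tsv")))
        write_tsv(as.data.frame(ses$csf_pool[[rn]]),
                  file.path(sd, paste0("csf_", rn, ".tsv")))
      }
      for (roi in names(ses$rois)) {
        rr <- ses$rois[[roi]]
        for (rn in c("pre_rs", "task", "post_rs")) {
          f <- file.path(sd, paste0("roi_", roi, "_", rn, ".tsv"))
          con <- file(f, "w")
          writeLines(sprintf("#tr %.10g", rr[[rn]]$tr), con)
          close(con)
          suppressWarnings(
            write.table(rr[[rn]]$data, f, sep = "\t", quote = FALSE,
                        row.names = FALSE, append = TRUE))
        }
        write_tsv(data.frame(voxel_id = rr$pre_rs$voxel_ids,
                             gm_prob = rr$gm_prob),
                  file.path(sd, paste0("gm_", roi, ".tsv")))
      }
      write_tsv(ses$rois[[1]]$task$block_annotations,
                file.path(sd, "annotations_task.tsv"))
    }
  }
  invisible(dir)
}

#' Read a time-series TSV written by [write_study()]
#'
#' @param path file path; first line `#tr <seconds>`, then a voxel-id
#'   header and one row per volume.
#' @param block_annotations optional annotation data frame to attach.
#' @return a [roi_ts()].
#' @export
read_roi_tsv <- function(path, block_annotations = NULL) {
  tr_line <- readLines(path, n = 1)
  if (!grepl("^#tr ", tr_line))
    stop_mvcsi("mvcsi_invalid", "missing '#tr' header in %s", path)
  tr <- as.numeric(sub("^#tr ", "", tr_line))
  x <- utils::read.delim(path, skip = 1, check.names = FALSE)
  roi_ts(as.matrix(x), tr = tr, voxel_ids = colnames(x),
         block_annotations = block_annotations)
}

#' Read a study directory back into memory
#'
#' @param dir directory written by [write_study()].
#' @return a `synth_study` object.
#' @export
read_study <- function(dir) {
  diag <- validate_inputs(dir)
  if (length(diag$errors))
    stop_mvcsi("mvcsi_invalid", "invalid study directory:\n  %s",
               paste(diag$errors, collapse = "\n  "))
  design <- read_tsv(file.path(dir, "design.tsv"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cfg$rois <- unlist(cfg$rois)
  cfg$rho <- unlist(cfg$rho)
  cfg$si_effects <- unlist(cfg$si_effects)
  class(cfg) <- "synth_config"
  gt <- read_tsv(file.path(dir, "ground_truth.tsv"))
  sessions <- list()
  for (s in unique(design$subject)) {
    sessions[[s]] <- list()
    for (cond in design$condition[design$subject == s]) {
      sd <- file.path(dir, paste0(s, "_", cond))
      ann <- read_tsv(file.path(sd, "annotations_task.tsv"))
      ses <- list(visit = design$visit[design$subject == s &
                                         design$condition == cond],
                  motion = list(), wm_pool = list(), csf_pool = list(),
                  rois = list(),
                  keypresses = read_tsv(file.path(sd, "keypresses.tsv")))
      for (rn in c("pre_rs", "task", "post_rs")) {
        ses$motion[[rn]] <-
          motion_params(read_tsv(file.path(sd, paste0("motion_", rn,
                                                      ".tsv"))))
        ses$wm_pool[[rn]] <-
          as.matrix(read_tsv(file.path(sd, paste0("wm_", rn, ".tsv"))))
        ses$csf_pool[[rn]] <-
          as.matrix(read_tsv(file.path(sd, paste0("csf_", rn, ".tsv"))))
      }
      for (roi in names(cfg$rois)) {
        gm <- read_tsv(file.path(sd, paste0("gm_", roi, ".tsv")))
        rr <- list()
        for (rn in c("pre_rs", "task", "post_rs"))
          rr[[rn]] <- read_roi_tsv(
            file.path(sd, paste0("roi_", roi, "_", rn, ".tsv")),
            block_annotations = if (rn == "task") ann)
        rr$gm_prob <- gm$gm_prob
        ses$rois[[roi]] <- rr
      }
      sessions[[s]][[cond]] <- ses
    }
  }
  structure(list(config = cfg, design = design, ground_truth = gt,
                 sessions = sessions), class = "synth_study")
}

#' Validate an on-disk study directory
#'
#' Checks the layout written by [write_study()]: presence of the design
#' table and config, uniqueness of subject x condition rows, presence and
#' shape of every per-session file (6-column motion tables whose row
#' counts match their runs, gray-matter tables matching the voxel count),
#' and the task annotation schedule. Hard violations are collected as
#' errors, soft issues as warnings; nothing is thrown.
#'
#' @param dir study directory.
#' @return list with character vectors `errors` and `warnings`.
#' @export
validate_inputs <- function(dir) {
  errors <- character(0); warnings <- character(0)
  err <- function(...) errors <<- c(errors, sprintf(...))
  if (!dir.exists(dir)) {
    err("study directory does not exist: %s", dir)
    return(list(errors = errors, warnings = warnings))
  }
  dfile <- file.path(dir, "design.tsv")
  if (!file.exists(dfile)) {
    err("missing design.tsv")
    return(list(errors = errors, warnings = warnings))
  }
  design <- read_tsv(dfile)
  need <- c("subject", "visit", "stimulation", "task", "condition")
  if (!all(need %in% names(design))) {
    err("design.tsv lacks columns: %s",
        paste(setdiff(need, names(design)), collapse = ", "))
    return(list(errors = errors, warnings = warnings))
  }
  if (anyDuplicated(paste(design$subject, design$condition)))
    err("design.tsv has duplicate subject x condition rows")
  cfile <- file.path(dir, "config.json")
  rois <- NULL
  if (!file.exists(cfile)) err("missing config.json")
  else rois <- names(unlist(jsonlite::read_json(cfile)$rois))
  for (i in seq_len(nrow(design))) {
    s <- design$subject[i]; cond <- design$condition[i]
    sd <- file.path(dir, paste0(s, "_", cond))
    if (!dir.exists(sd)) { err("missing session directory %s", sd); next }
    if (!file.exists(file.path(sd, "keypresses.tsv")))
      err("%s: missing keypresses.tsv", basename(sd))
    for (rn in c("pre_rs", "task", "post_rs")) {
      mf <- file.path(sd, paste0("motion_", rn, ".tsv"))
      if (!file.exists(mf)) { err("%s: missing motion file motion_%s.tsv",
                                  basename(sd), rn); next }
      mo <- read_tsv(mf)
      if (ncol(mo) != 6)
        err("%s: motion_%s.tsv has %d columns, expected 6",
            basename(sd), rn, ncol(mo))
      for (roi in rois) {
        rf <- file.path(sd, paste0("roi_", roi, "_", rn, ".tsv"))
        if (!file.exists(rf)) {
          err("%s: missing run file roi_%s_%s.tsv", basename(sd), roi, rn)
          next
        }
        n_vol <- length(readLines(rf)) - 2L
        if (n_vol != nrow(mo))
          err("%s: roi_%s_%s.tsv has %d volumes but motion has %d rows",
              basename(sd), roi, rn, n_vol, nrow(mo))
      }
    }
    for (roi in rois)
      if (!file.exists(file.path(sd, paste0("gm_", roi, ".tsv"))))
        err("%s: missing gm_%s.tsv", basename(sd), roi)
    if (!file.exists(file.path(sd, "annotations_task.tsv")))
      err("%s: missing annotations_task.tsv", basename(sd))
  }
  cells <- table(design$subject)
  if (any(cells < 4))
    warnings <- c(warnings,
                  sprintf("incomplete subjects (fewer than 4 sessions): %s",
                          paste(names(cells)[cells < 4], collapse = ", ")))
  list(errors = errors, warnings = warnings)
}

#' Write the report tables of a pipeline run
#'
#' Writes `si_table.tsv`, `lmm_table.tsv`, `followups.tsv`,
#' `behavior_blocks.tsv`, `exclusions.tsv` and `provenance.json` to a
#' directory. Re-running the pipeline with the same configuration and
#' seed reproduces these files byte for byte.
#'
#' @param report a [run_pipeline()] result.
#' @param dir target directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$si_table, file.path(dir, "si_table.tsv"))
  if (!is.null(report$lmm_table))
    write_tsv(report$lmm_table, file.path(dir, "lmm_table.tsv"))
  if (!is.null(report$followups))
    write_tsv(report$followups, file.path(dir, "followups.tsv"))
  write_tsv(report$behavior_blocks, file.path(dir, "behavior_blocks.tsv"))
  write_tsv(report$exclusions, file.path(dir, "exclusions.tsv"))
  jsonlite::write_json(
    list(seed = report$provenance$seed,
         package_version = report$provenance$package_version,
         omitted = report$omitted),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Extract an ROI time-series from NIfTI files
#'
#' Convenience reader for users with imaging data: loads a 4D NIfTI run
#' and a 3D mask (non-zero voxels define the ROI) and returns the
#' time-by-voxel matrix as a [roi_ts()]. Requires the RNifti package.
#'
#' @param bold_file path to the 4D functional NIfTI.
#' @param mask_file path to the 3D ROI mask NIfTI (same grid).
#' @param tr repetition time in seconds; taken from the NIfTI header
#'   `pixdim[4]` when omitted.
#' @return a [roi_ts()] with voxel ids `x_y_z` from the mask coordinates.
#' @export
extract_roi_nifti <- function(bold_file, mask_file, tr = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop_mvcsi("mvcsi_invalid",
               "the RNifti package is required for NIfTI input")
  bold <- RNifti::readNifti(bold_file)
  mask <- RNifti::readNifti(mask_file)
  if (length(dim(bold)) != 4L)
    stop_mvcsi("mvcsi_invalid", "expected a 4D functional image")
  if (!all(dim(bold)[1:3] == dim(mask)[1:3]))
    stop_mvcsi("mvcsi_invalid", "mask grid does not match functional grid")
  vox <- which(mask != 0, arr.ind = TRUE)
  if (nrow(vox) == 0L) stop_mvcsi("mvcsi_invalid", "empty mask")
  n_t <- dim(bold)[4]
  flat <- matrix(bold, prod(dim(bold)[1:3]), n_t)
  lin <- (vox[, 3] - 1) * dim(bold)[1] * dim(bold)[2] +
    (vox[, 2] - 1) * dim(bold)[1] + vox[, 1]
  if (is.null(tr)) {
    tr <- RNifti::pixdim(bold)[4]
    if (!is.finite(tr) || tr <= 0)
      stop_mvcsi("mvcsi_invalid", "TR not available from header; pass 'tr'")
  }
  roi_ts(t(flat[lin, , drop = FALSE]), tr = tr,
         voxel_ids = apply(vox, 1, paste, collapse = "_"))
}
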