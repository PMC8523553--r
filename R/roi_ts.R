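#' ROI voxel time series
#'
#' The basic data unit of the pipeline: one fMRI run restricted to a region
#' of interest, stored as a time-by-voxel matrix together with its repetition
#' time, the original volume indices still present (so that scrubbing and
#' volume matching can be tracked), stable voxel identifiers, and, for task
#' runs, practice/rest block annotations.
#'
#' @param data numeric matrix, volumes in rows, voxels in columns.
#' @param tr repetition time in seconds.
#' @param frame_index integer vector of original (1-based) volume indices
#'   retained in `data`; must be strictly increasing and match `nrow(data)`.
#'   Defaults to `1:nrow(data)`.
#' @param voxel_ids character vector of unique voxel labels; defaults to
#'   `"v1" ... "vN"`.
#' @param block_annotations optional data frame with columns `block`, `phase`
#'   (`"practice"` or `"rest"`), `start_vol`, `end_vol` giving 1-based volume
#'   ranges of the task schedule on the original volume grid.
#' @return an object of class `roi_ts`.
#' @export
roi_ts <- function(data, tr, frame_index = NULL, voxel_ids = NULL,
                   block_annotations = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop_mvcsi("mvcsi_invalid", "'tr' must be a single positive number")
  if (is.null(frame_index)) frame_index <- seq_len(nrow(data))
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != nrow(data))
    stop_mvcsi("mvcsi_invalid",
               "'frame_index' length (%d) must equal nrow(data) (%d)",
               length(frame_index), nrow(data))
  if (length(frame_index) > 1L && any(diff(frame_index) <= 0L))
    stop_mvcsi("mvcsi_invalid", "'frame_index' must be strictly increasing")
  if (is.null(voxel_ids)) voxel_ids <- paste0("v", seq_len(ncol(data)))
  voxel_ids <- as.character(voxel_ids)
  if (length(voxel_ids) != ncol(data))
    stop_mvcsi("mvcsi_invalid", "'voxel_ids' length must equal ncol(data)")
  if (anyDuplicated(voxel_ids))
    stop_mvcsi("mvcsi_invalid", "duplicate voxel_ids")
  colnames(data) <- voxel_ids
  structure(list(data = data, tr = tr, frame_index = frame_index,
                 voxel_ids = voxel_ids,
                 block_annotations = block_annotations),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("ROI time series: %d volumes x %d voxels, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$tr))
  if (!is.null(x$block_annotations))
    cat(sprintf("  task schedule: %d practice blocks\n",
                sum(x$block_annotations$phase == "practice")))
  dropped <- length(x$frame_index) &&
    (max(x$frame_index) > length(x$frame_index))
  if (dropped)
    cat(sprintf("  frames retained: %d of >= %d original volumes\n",
                length(x$frame_index), max(x$frame_index)))
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

# Subset volumes (rows) of a run, keeping bookkeeping consistent.
subset_volumes <- function(run, rows) {
  rows <- as.integer(rows)
  roi_ts(run$data[rows, , drop = FALSE], tr = run$tr,
         frame_index = run$frame_index[rows], voxel_ids = run$voxel_ids,
         block_annotations = run$block_annotations)
}

# Subset voxels (columns) by index or id.
subset_voxels <- function(run, cols) {
  roi_ts(run$data[, cols, drop = FALSE], tr = run$tr,
         frame_index = run$frame_index,
         voxel_ids = run$voxel_ids[if (is.character(cols))
           match(cols, run$voxel_ids) else cols],
         block_annotations = run$block_annotations)
}

#' Six-parameter head motion table
#'
#' Validates a per-volume rigid-body realignment parameter table: three
#' translations in millimetres followed by three rotations in radians.
#'
#' @param x numeric matrix or data frame with 6 columns and one row per
#'   acquired volume.
#' @return a numeric matrix of class `motion_params` with canonical column
#'   names `trans_x_mm, trans_y_mm, trans_z_mm, rot_x_rad, rot_y_rad,
#'   rot_z_rad`.
#' @export
motion_params <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 6L)
    stop_mvcsi("mvcsi_invalid",
               "motion table must have 6 columns, got %d", ncol(x))
  colnames(x) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                   "rot_x_rad", "rot_y_rad", "rot_z_rad")
  class(x) <- c("motion_params", class(x))
  x
}
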