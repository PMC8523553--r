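#' Fisher r-to-z transform
#'
#' `arctanh(r)`, used to bring correlation coefficients onto an unbounded,
#' approximately normal scale before averaging or modelling.
#'
#' @param r correlation value(s) with `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop_mvcsi("mvcsi_degenerate_correlation",
               "|r| >= 1: Fisher z is undefined")
  atanh(r)
}

# Clip bound used when a voxel pair is perfectly (anti)correlated: the pair
# is kept but its entry saturates at atanh(1 - 1e-7) so downstream
# similarity values stay finite.
.z_clip <- atanh(1 - 1e-7)

#' Multivoxel correlation structure of one run
#'
#' Pairwise Pearson correlations between all voxel time courses of an ROI
#' run, Fisher z-transformed off the diagonal. The diagonal is stored as 0
#' and excluded from all downstream use. Voxels with zero variance are
#' removed (and recorded); perfectly correlated voxel pairs are retained
#' with the entry clipped to `atanh(1 - 1e-7)` and a warning.
#'
#' @param run a [roi_ts()] with at least 3 voxels and 3 volumes.
#' @param roi,label optional ROI and run labels carried in the result.
#' @return an object of class `mvcs_matrix`: list with the symmetric `z`
#'   matrix, voxel count `n`, `voxel_ids`, labels, and `dropped_voxels`.
#' @export
compute_mvcs <- function(run, roi = NA_character_, label = NA_character_) {
  stopifnot(inherits(run, "roi_ts"))
  x <- run$data
  if (nrow(x) < 3L)
    stop_mvcsi("mvcsi_invalid", "need >= 3 volumes, got %d", nrow(x))
  v <- apply(x, 2, stats::var)
  dropped <- run$voxel_ids[!is.finite(v) | v <= 0]
  if (length(dropped)) {
    x <- x[, is.finite(v) & v > 0, drop = FALSE]
  }
  if (ncol(x) < 3L)
    stop_mvcsi("mvcsi_invalid",
               "need >= 3 voxels with non-zero variance, got %d", ncol(x))
  r <- cor(x)
  off <- row(r) != col(r)
  if (any(abs(r[off]) >= 1 - 1e-12)) {
    warning("perfectly correlated voxel pair(s); z clipped")
    r[off][r[off] >= 1 - 1e-12] <- 1 - 1e-7
    r[off][r[off] <= -1 + 1e-12] <- -(1 - 1e-7)
  }
  z <- r
  z[off] <- atanh(r[off])
  diag(z) <- 0
  structure(list(z = z, n = ncol(x), voxel_ids = colnames(x),
                 roi = roi, label = label, dropped_voxels = dropped),
            class = "mvcs_matrix")
}

#' @export
print.mvcs_matrix <- function(x, ...) {
  cat(sprintf("MVCS matrix: %d voxels%s%s\n", x$n,
              if (is.na(x$roi)) "" else paste0(", ROI ", x$roi),
              if (is.na(x$label)) "" else paste0(", run ", x$label)))
  if (length(x$dropped_voxels))
    cat(sprintf("  %d zero-variance voxel(s) dropped\n",
                length(x$dropped_voxels)))
  invisible(x)
}

#' Similarity index between two MVCS matrices
#'
#' Pearson correlation between the vectorised strict upper triangles of the
#' two matrices, Fisher z-transformed. The matrices are aligned on their
#' common voxel identifiers first, so a voxel dropped in one run (e.g. zero
#' variance) does not break the element-wise comparability of the
#' triangles. Symmetric in its arguments.
#'
#' @param a,b [compute_mvcs()] results for the two runs.
#' @return the similarity index (r-to-z scale) with attributes `n_voxels`
#'   (common voxels used) and `r` (the untransformed correlation).
#' @export
similarity_index <- function(a, b) {
  stopifnot(inherits(a, "mvcs_matrix"), inherits(b, "mvcs_matrix"))
  common <- intersect(a$voxel_ids, b$voxel_ids)
  if (length(common) < 3L)
    stop_mvcsi("mvcsi_invalid",
               "fewer than 3 voxels shared between the two matrices")
  za <- a$z[common, common]
  zb <- b$z[common, common]
  ut <- upper.tri(za)
  r <- cor(za[ut], zb[ut])
  if (!is.finite(r))
    stop_mvcsi("mvcsi_degenerate_similarity",
               "similarity undefined (constant triangle)")
  if (abs(r) >= 1)
    stop_mvcsi("mvcsi_degenerate_similarity",
               "|r| = 1 between MVCS matrices; similarity index infinite")
  si <- atanh(r)
  attr(si, "n_voxels") <- length(common)
  attr(si, "r") <- r
  si
}

#' Split a task run into early and late practice halves
#'
#' Uses the run's practice/rest block annotations to cut the time series at
#' the boundary between the rest period following practice block
#' `n_blocks / 2` and the onset of the next practice block. Volumes are
#' assigned by their original volume index, so the split is stable under
#' prior censoring.
#'
#' @param task_run a [roi_ts()] with `block_annotations`.
#' @return list with `early` and `late` [roi_ts()] halves; together they
#'   partition the input volumes in order.
#' @export
split_early_late <- function(task_run) {
  stopifnot(inherits(task_run, "roi_ts"))
  ann <- task_run$block_annotations
  if (is.null(ann))
    stop_mvcsi("mvcsi_invalid", "task run has no block annotations")
  prac <- ann[ann$phase == "practice", , drop = FALSE]
  n_blocks <- nrow(prac)
  if (n_blocks < 2L || n_blocks %% 2L != 0L)
    stop_mvcsi("mvcsi_invalid",
               "need an even number of practice blocks, got %d", n_blocks)
  first_late <- prac$start_vol[prac$block == (n_blocks / 2 + 1)]
  early_rows <- which(task_run$frame_index < first_late)
  late_rows <- which(task_run$frame_index >= first_late)
  if (length(early_rows) < 2L || length(late_rows) < 2L)
    stop_mvcsi("mvcsi_invalid", "degenerate early/late split")
  list(early = subset_volumes(task_run, early_rows),
       late = subset_volumes(task_run, late_rows))
}

#' Similarity indices for the three run pairings of one session
#'
#' For one subject x condition x ROI, computes the similarity index for
#' (1) early vs late task practice, (2) pre- vs post-intervention rest, and
#' (3) the entire task run vs post-intervention rest. Runs are expected to
#' be fully preprocessed except for pair-level volume matching, which is
#' applied here; for pairing (3), supply the task-TR down-sampled post-rest
#' run via `post_rs_at_task_tr` (pairings mixing repetition times compare
#' runs at the slower TR). Missing runs yield missing records rather than
#' an error; unusable pairs are dropped with a reason.
#'
#' @param pre_rs,post_rs preprocessed rest runs (may be `NULL` if the run
#'   was dropped); `post_rs_at_task_tr` the post-rest run preprocessed at
#'   the task TR (may be `NULL`).
#' @param task preprocessed task run with block annotations (may be `NULL`).
#' @param meta named list or one-row data frame of record keys (e.g.
#'   subject, visit, stimulation, task, condition, roi).
#' @param min_volumes minimum matched pair length (default 30).
#' @return data frame with one row per computed pairing: the `meta` columns
#'   plus `pairing`, `si`, `n_voxels`, `n_volumes`; attribute `omitted`
#'   lists pairings that could not be computed and why.
#' @export
assemble_pairings <- function(task = NULL, pre_rs = NULL, post_rs = NULL,
                              post_rs_at_task_tr = NULL, meta = list(),
                              min_volumes = 30) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  rows <- list()
  omitted <- list()
  add <- function(pairing, run_a, run_b) {
    if (is.null(run_a) || is.null(run_b)) {
      omitted[[pairing]] <<- "run missing"
      return(invisible())
    }
    rec <- tryCatch({
      m <- match_volumes(run_a, run_b, min_volumes = min_volumes)
      si <- similarity_index(compute_mvcs(m$a), compute_mvcs(m$b))
      cbind(meta, data.frame(pairing = pairing, si = as.numeric(si),
                             n_voxels = attr(si, "n_voxels"),
                             n_volumes = nrow(m$a$data)))
    }, mvcsi_error = function(e) {
      omitted[[pairing]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(rec)) rows[[pairing]] <<- rec
  }
  halves <- if (!is.null(task)) {
    tryCatch(split_early_late(task), mvcsi_error = function(e) {
      omitted[["early_late"]] <<- conditionMessage(e)
      NULL
    })
  }
  if (!is.null(halves)) add("early_late", halves$early, halves$late)
  add("rs_pre_post", pre_rs, post_rs)
  add("task_rs_post", task, post_rs_at_task_tr)
  out <- if (length(rows)) do.call(rbind, unname(rows)) else
    cbind(meta[0, , drop = FALSE],
          data.frame(pairing = character(0), si = numeric(0),
                     n_voxels = integer(0), n_volumes = integer(0)))
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}
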