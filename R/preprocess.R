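#' Detrend and high-pass filter an ROI run
#'
#' Removes, per voxel, the mean, a linear trend, and all discrete-cosine
#' basis functions with frequency below `cutoff_hz` (i.e. periods longer than
#' `1/cutoff_hz` seconds). The projection is exactly linear, so filtering a
#' signal twice is a no-op and output variance never exceeds input variance.
#'
#' @param run a [roi_ts()] object with at least 8 volumes.
#' @param cutoff_hz high-pass cutoff in Hz; the default 1/128 removes
#'   fluctuations slower than 128 s.
#' @return a [roi_ts()] of the same shape with filtered data.
#' @export
detrend_highpass <- function(run, cutoff_hz = 1 / 128) {
  stopifnot(inherits(run, "roi_ts"))
  n <- nrow(run$data)
  if (n < 8L)
    stop_mvcsi("mvcsi_invalid", "need >= 8 volumes to filter, got %d", n)
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0)
    stop_mvcsi("mvcsi_invalid", "'cutoff_hz' must be positive")
  X <- highpass_basis(n, run$tr, cutoff_hz)
  if (ncol(X) >= n)
    stop_mvcsi("mvcsi_invalid",
               "cutoff %g Hz implies a full basis (%d columns for %d volumes)",
               cutoff_hz, ncol(X), n)
  res <- qr.resid(qr(X), run$data)
  dimnames(res) <- dimnames(run$data)
  out <- run
  out$data <- res
  out
}

# Intercept + linear trend + DCT-II regressors below the cutoff frequency.
# The k-th cosine has frequency k / (2 * n * tr) Hz; columns with frequency
# < cutoff are included (periods strictly longer than 1/cutoff).
highpass_basis <- function(n, tr, cutoff_hz) {
  t0 <- seq_len(n) - 1
  X <- cbind(1, t0 - mean(t0))
  k_max <- floor(2 * n * tr * cutoff_hz)
  if (k_max >= 1) {
    dct <- vapply(seq_len(k_max),
                  function(k) cos(pi * k * (2 * t0 + 1) / (2 * n)),
                  numeric(n))
    X <- cbind(X, dct)
  } else {
    stop_mvcsi("mvcsi_invalid",
               "cutoff %g Hz yields an empty cosine basis for this run",
               cutoff_hz)
  }
  X
}

#' Framewise displacement from realignment parameters
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the three translations (mm) plus the three rotations
#' converted to arc length on a 50 mm sphere. The first volume has FD 0 by
#' convention.
#'
#' @param motion a [motion_params()] table (or 6-column matrix).
#' @param rotation_radius_mm radius used to convert rotations to mm.
#' @return numeric vector of per-volume displacements (mm) with attribute
#'   `rotation_radius_mm`.
#' @export
compute_fd <- function(motion, rotation_radius_mm = 50) {
  motion <- motion_params(motion)
  n <- nrow(motion)
  if (n < 1L) stop_mvcsi("mvcsi_invalid", "motion table is empty")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  attr(fd, "rotation_radius_mm") <- rotation_radius_mm
  fd
}

#' Scrub high-motion volumes
#'
#' Removes every volume whose framewise displacement exceeds the threshold
#' together with the volume immediately following it (if any). Temporal
#' order is preserved and `frame_index` keeps pointing at the original
#' volume numbers.
#'
#' @param run a [roi_ts()] object.
#' @param fd framewise displacement vector, one value per row of `run$data`
#'   (see [compute_fd()]).
#' @param threshold_mm scrubbing threshold in mm (default 0.5).
#' @return the censored [roi_ts()]; attribute `censored` holds the row
#'   indices removed and `censored_fraction` the fraction of volumes lost.
#' @export
censor_frames <- function(run, fd, threshold_mm = 0.5) {
  stopifnot(inherits(run, "roi_ts"))
  n <- nrow(run$data)
  if (length(fd) != n)
    stop_mvcsi("mvcsi_invalid",
               "fd length (%d) must equal run volume count (%d)",
               length(fd), n)
  bad <- censored_rows(fd, threshold_mm)
  keep <- setdiff(seq_len(n), bad)
  if (length(keep) == 0L)
    stop_mvcsi("mvcsi_run_unusable", "all %d volumes censored", n)
  out <- subset_volumes(run, keep)
  attr(out, "censored") <- bad
  attr(out, "censored_fraction") <- length(bad) / n
  out
}

# Row indices removed by the scrubbing rule: each exceedance plus successor.
censored_rows <- function(fd, threshold_mm) {
  over <- which(fd > threshold_mm)
  sort(unique(c(over, over + 1L)[c(over, over + 1L) <= length(fd)]))
}

#' Down-sample a run to a slower repetition time
#'
#' Linear interpolation of every voxel time course onto the grid
#' `0, target_tr, 2 * target_tr, ...` (seconds from run onset) within the
#' original time span. Used when a run pair mixes repetition times: the
#' faster run is brought down to the slower one. Up-sampling is refused.
#' Must be applied before scrubbing (it assumes a regular grid).
#'
#' @param run a [roi_ts()] with a complete (uncensored) volume grid.
#' @param target_tr target repetition time in seconds, `>= run$tr`.
#' @return a [roi_ts()] on the new grid with `tr = target_tr`.
#' @export
resample_to_tr <- function(run, target_tr) {
  stopifnot(inherits(run, "roi_ts"))
  if (target_tr < run$tr)
    stop_mvcsi("mvcsi_invalid",
               "refusing to up-sample: target TR %g < run TR %g",
               target_tr, run$tr)
  if (length(run$frame_index) != max(run$frame_index))
    stop_mvcsi("mvcsi_invalid",
               "resampling requires an uncensored run (regular time grid)")
  if (target_tr == run$tr) return(run)
  new_data <- resample_matrix(run$data, run$tr, target_tr)
  roi_ts(new_data, tr = target_tr, voxel_ids = run$voxel_ids,
         block_annotations = rescale_annotations(run$block_annotations,
                                                 run$tr, target_tr))
}

# Shared interpolation core so data, motion and nuisance pools are
# down-sampled by the same operator.
resample_matrix <- function(x, tr, target_tr) {
  n <- nrow(x)
  t_old <- (seq_len(n) - 1) * tr
  t_new <- seq(0, t_old[n], by = target_tr)
  out <- apply(x, 2, function(v) approx(t_old, v, xout = t_new)$y)
  if (is.null(dim(out))) out <- matrix(out, nrow = length(t_new))
  colnames(out) <- colnames(x)
  out
}

rescale_annotations <- function(ann, tr, target_tr) {
  if (is.null(ann)) return(NULL)
  ratio <- tr / target_tr
  ann$start_vol <- pmax(1L, as.integer(ceiling((ann$start_vol - 1) * ratio) + 1L))
  ann$end_vol <- as.integer(floor((ann$end_vol - 1) * ratio) + 1L)
  ann
}

#' Expanded head-motion nuisance regressors
#'
#' The six realignment parameters, their squares, their backward-difference
#' derivatives (first row zero), and the squared derivatives: 24 columns.
#'
#' @param motion a [motion_params()] table (or 6-column matrix).
#' @return numeric matrix with 24 labelled columns, one row per volume.
#' @export
build_motion_regressors <- function(motion) {
  motion <- motion_params(motion)
  m <- unclass(motion)
  d <- rbind(0, diff(m))
  out <- cbind(m, m^2, d, d^2)
  colnames(out) <- c(colnames(m), paste0(colnames(m), "_sq"),
                     paste0(colnames(m), "_deriv"),
                     paste0(colnames(m), "_deriv_sq"))
  out
}

#' Principal-component tissue regressors from WM and CSF signal pools
#'
#' Column-demeans each pool and extracts the first `k` principal-component
#' time courses (unit norm, sign fixed so the largest-magnitude loading is
#' positive), concatenating white-matter and CSF components.
#'
#' @param wm_pool,csf_pool time-by-signal matrices of white-matter and
#'   cerebrospinal-fluid voxel/parcel signals with matching row counts.
#' @param k components per tissue (default 3).
#' @return matrix with up to `2 * k` columns (`wm_pc1..., csf_pc1...`). If a
#'   pool has rank below `k`, the available components are returned and the
#'   attribute `rank_deficient` is set.
#' @export
extract_tissue_components <- function(wm_pool, csf_pool, k = 3) {
  comp <- function(pool, label) {
    pool <- as.matrix(pool)
    if (ncol(pool) < k)
      stop_mvcsi("mvcsi_invalid",
                 "%s pool has %d signals, need >= k = %d", label,
                 ncol(pool), k)
    pc <- prcomp(pool, center = TRUE, scale. = FALSE)
    keep <- min(k, sum(pc$sdev > max(pc$sdev) * 1e-10))
    sc <- pc$x[, seq_len(keep), drop = FALSE]
    for (j in seq_len(keep)) {
      nrm <- sqrt(sum(sc[, j]^2))
      if (nrm > 0) sc[, j] <- sc[, j] / nrm
      load <- pc$rotation[, j]
      if (load[which.max(abs(load))] < 0) sc[, j] <- -sc[, j]
    }
    colnames(sc) <- paste0(label, "_pc", seq_len(keep))
    list(scores = sc, deficient = keep < k)
  }
  wm <- comp(wm_pool, "wm")
  cs <- comp(csf_pool, "csf")
  if (nrow(wm$scores) != nrow(cs$scores))
    stop_mvcsi("mvcsi_invalid", "WM and CSF pools have different volume counts")
  out <- cbind(wm$scores, cs$scores)
  if (wm$deficient || cs$deficient) {
    warning("tissue pool rank below k; returning available components")
    attr(out, "rank_deficient") <- TRUE
  }
  out
}

#' Regress nuisance signals out of an ROI run
#'
#' Per voxel, replaces the time course with the residual of a least-squares
#' fit on an intercept plus the supplied nuisance columns. Residuals are
#' numerically orthogonal to every retained regressor. Collinear columns are
#' dropped (with a message naming them).
#'
#' @param run a [roi_ts()] object.
#' @param nuis time-by-regressor matrix whose rows match `run$data` (censor
#'   regressors with the same frame mask first), or `NULL` to just demean.
#' @return a [roi_ts()] of residuals; attribute `dropped_regressors` names
#'   collinear columns that were excluded.
#' @export
regress_nuisance <- function(run, nuis = NULL) {
  stopifnot(inherits(run, "roi_ts"))
  n <- nrow(run$data)
  if (is.null(nuis) || ncol(as.matrix(nuis)) == 0L) {
    X <- matrix(1, n, 1)
    dropped <- character(0)
  } else {
    nuis <- as.matrix(nuis)
    if (nrow(nuis) != n)
      stop_mvcsi("mvcsi_invalid",
                 "nuisance rows (%d) must match run volumes (%d)",
                 nrow(nuis), n)
    if (is.null(colnames(nuis)))
      colnames(nuis) <- paste0("nuis", seq_len(ncol(nuis)))
    X <- cbind("(Intercept)" = 1, nuis)
    qx <- qr(X)
    dropped <- character(0)
    if (qx$rank < ncol(X)) {
      keep <- qx$pivot[seq_len(qx$rank)]
      dropped <- setdiff(colnames(X), colnames(X)[keep])
      message("dropping collinear nuisance columns: ",
              paste(dropped, collapse = ", "))
      X <- X[, keep, drop = FALSE]
    }
  }
  res <- qr.resid(qr(X), run$data)
  dimnames(res) <- dimnames(run$data)
  out <- run
  out$data <- res
  attr(out, "dropped_regressors") <- dropped
  out
}

#' Restrict an ROI run to gray-matter voxels
#'
#' Keeps voxels whose gray-matter probability strictly exceeds the
#' threshold. Voxel identifiers are preserved so runs of the same ROI stay
#' aligned.
#'
#' @param run a [roi_ts()] object.
#' @param gm_prob per-voxel gray-matter probability in `[0, 1]`, aligned
#'   with `run$voxel_ids`.
#' @param threshold exclusion threshold (default 0.10; strict `>`).
#' @return the voxel-subset [roi_ts()].
#' @export
select_voxels_gm <- function(run, gm_prob, threshold = 0.10) {
  stopifnot(inherits(run, "roi_ts"))
  if (length(gm_prob) != ncol(run$data))
    stop_mvcsi("mvcsi_invalid",
               "gm_prob length (%d) must equal voxel count (%d)",
               length(gm_prob), ncol(run$data))
  keep <- which(gm_prob > threshold)
  if (length(keep) == 0L)
    stop_mvcsi("mvcsi_roi_unusable",
               "no voxel exceeds GM probability %g", threshold)
  subset_voxels(run, keep)
}

#' Match volume counts of a run pair
#'
#' The run with more retained volumes is trimmed to a centred window of
#' length `x`, where `x` is the volume count of the shorter run: the window
#' starts at position `floor((N - x) / 2)` (0-based) within the longer run's
#' retained sequence. The shorter run is returned unchanged.
#'
#' @param a,b [roi_ts()] objects at a common TR, already censored.
#' @param min_volumes minimum usable pair length (default 30); shorter pairs
#'   raise a `mvcsi_pair_unusable` error.
#' @return list with elements `a` and `b`, both with `x` rows.
#' @export
match_volumes <- function(a, b, min_volumes = 30) {
  stopifnot(inherits(a, "roi_ts"), inherits(b, "roi_ts"))
  if (abs(a$tr - b$tr) > 1e-9)
    stop_mvcsi("mvcsi_invalid", "runs must share a TR (got %g and %g)",
               a$tr, b$tr)
  x <- min(nrow(a$data), nrow(b$data))
  if (x < min_volumes)
    stop_mvcsi("mvcsi_pair_unusable",
               "only %d matched volumes (< %d required)", x, min_volumes)
  trim <- function(run) {
    n <- nrow(run$data)
    if (n == x) return(run)
    start <- floor((n - x) / 2)  # 0-based offset into the retained sequence
    subset_volumes(run, seq.int(start + 1L, start + x))
  }
  list(a = trim(a), b = trim(b))
}
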