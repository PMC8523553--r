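#' Spherical ROI mask on a voxel grid
#'
#' Builds the set of voxels whose centres lie within `radius_mm` (Euclidean,
#' inclusive) of a point, on an axis-aligned grid with the given spacing.
#' This is the construction used for a stimulation-target ROI: a 10 mm
#' radius sphere around an individually defined coordinate.
#'
#' @param center_mm numeric length-3 centre coordinate (mm).
#' @param radius_mm sphere radius in mm (default 10).
#' @param spacing_mm voxel size, scalar or length-3 (default 2).
#' @return an object of class `roi_mask`: a list with integer coordinate
#'   matrix `coords` (voxel grid indices, one row per voxel) and
#'   `spacing_mm`. Grid index `k` corresponds to world coordinate
#'   `k * spacing_mm` along each axis; the second axis is the
#'   posterior-to-anterior direction.
#' @export
build_sphere_roi <- function(center_mm, radius_mm = 10, spacing_mm = 2) {
  if (radius_mm <= 0)
    stop_mvcsi("mvcsi_invalid", "'radius_mm' must be positive")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  stopifnot(length(center_mm) == 3L, all(spacing_mm > 0))
  rng <- lapply(1:3, function(ax) {
    lo <- floor((center_mm[ax] - radius_mm) / spacing_mm[ax])
    hi <- ceiling((center_mm[ax] + radius_mm) / spacing_mm[ax])
    seq.int(lo, hi)
  })
  grid <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  centre_dist2 <- (t(t(grid) * spacing_mm) -
                     matrix(center_mm, nrow(grid), 3, byrow = TRUE))^2
  keep <- rowSums(centre_dist2) <= radius_mm^2 + 1e-9
  if (!any(keep))
    stop_mvcsi("mvcsi_invalid",
               "sphere of radius %g mm contains no voxel centre", radius_mm)
  roi_mask(grid[keep, , drop = FALSE], spacing_mm)
}

#' @rdname build_sphere_roi
#' @param coords integer matrix of voxel grid indices (columns x, y, z).
#' @export
roi_mask <- function(coords, spacing_mm = 2) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (nrow(coords) == 0L)
    stop_mvcsi("mvcsi_invalid", "empty mask")
  if (anyDuplicated(coords))
    stop_mvcsi("mvcsi_invalid", "duplicate voxel coordinates in mask")
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, spacing_mm = rep_len(spacing_mm, 3L)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask: %d voxels, spacing %s mm\n", nrow(x$coords),
              paste(x$spacing_mm, collapse = " x ")))
  invisible(x)
}

#' Split a mask into anterior and posterior halves
#'
#' Partitions an ROI mask at the middle slice of its coronal (second-axis)
#' extent: with occupied slices spanning `[y_min, y_max]`, the middle slice
#' is `m = floor((y_min + y_max) / 2)`; voxels with `y > m` form the
#' anterior part and voxels with `y <= m` the posterior part. Used for the
#' anterior/posterior hippocampus subdivision.
#'
#' @param mask an [roi_mask()] spanning at least two coronal slices.
#' @return list with `anterior` and `posterior` [roi_mask()] elements; the
#'   two parts partition the input exactly.
#' @export
split_mask_coronal <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  y <- mask$coords[, 2]
  if (length(unique(y)) < 2L)
    stop_mvcsi("mvcsi_invalid",
               "mask spans a single coronal slice; cannot split")
  m <- floor((min(y) + max(y)) / 2)
  list(anterior = roi_mask(mask$coords[y > m, , drop = FALSE],
                           mask$spacing_mm),
       posterior = roi_mask(mask$coords[y <= m, , drop = FALSE],
                            mask$spacing_mm))
}
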