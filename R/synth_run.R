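# Random loading matrix with unit-norm columns.
random_loadings <- function(n_voxels, n_factors) {
  w <- matrix(rnorm(n_voxels * n_factors), n_voxels, n_factors)
  unit_cols(w)
}

unit_cols <- function(w) {
  nrm <- sqrt(colSums(w^2))
  nrm[nrm == 0] <- 1
  sweep(w, 2, nrm, "/")
}

#' Mix two loading matrices with a persistence weight
#'
#' `sqrt(rho) * w_shared + sqrt(1 - rho) * w_new`, columns renormalised.
#' With `rho = 1` the shared structure is reproduced exactly; with
#' `rho = 0` the result is independent of `w_shared`. This is the single
#' knob through which the generator controls how much voxel-by-voxel
#' correlation structure two runs share.
#'
#' @param w_shared loading matrix whose structure should persist.
#' @param rho persistence weight in `[0, 1]`.
#' @param w_new independent loading matrix of the same shape; freshly drawn
#'   if omitted (uses the current RNG stream).
#' @return mixed loading matrix with unit-norm columns.
#' @export
mix_loadings <- function(w_shared, rho, w_new = NULL) {
  if (rho < 0 || rho > 1)
    stop_mvcsi("mvcsi_invalid", "field 'rho' must lie in [0, 1], got %g", rho)
  if (is.null(w_new))
    w_new <- matrix(rnorm(length(w_shared)), nrow(w_shared), ncol(w_shared))
  stopifnot(all(dim(w_new) == dim(w_shared)))
  unit_cols(sqrt(rho) * unit_cols(w_shared) + sqrt(1 - rho) * unit_cols(w_new))
}

# Smoothed white noise: moving average over ~window_s seconds, rescaled to
# unit variance. Used for latent factor and nuisance time courses; the
# correlation structure the pipeline measures lives in the loadings, not in
# any evoked response shape.
smooth_signal <- function(n, tr, window_s = 6) {
  w <- max(1L, round(window_s / tr))
  x <- rnorm(n + w)
  if (w > 1L) {
    x <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))
  }
  x <- x[(w + 1):(n + w)]
  s <- sd(x)
  if (s > 0) x / s else x
}

# Slow drift below 1/128 Hz: second-order polynomial plus one sinusoid with
# a random period between 160 s and 640 s.
drift_signals <- function(n, tr) {
  t_s <- (seq_len(n) - 1) * tr
  period <- runif(1, 160, 640)
  phase <- runif(1, 0, 2 * pi)
  u <- t_s / max(t_s[n], 1)
  cbind(poly1 = u - mean(u), poly2 = (u - 0.5)^2 - mean((u - 0.5)^2),
        sine = sin(2 * pi * t_s / period + phase))
}

#' Generate one synthetic ROI run
#'
#' Voxel time courses are built as
#' `loadings %*% factors(t) + drift + nuisance coupling + white noise`,
#' where the factor time courses are smoothed white noise (moving average
#' of about 6 s) and the noiseless voxel-by-voxel correlation structure is
#' determined entirely by the loading matrix, so two runs sharing loadings
#' share their multivoxel correlation structure.
#'
#' @param loadings voxel-by-factor matrix, or a list of such matrices for
#'   runs whose pattern structure switches; `switch_vols` then gives the
#'   first volume of each segment after the first.
#' @param n_volumes number of volumes (>= 2).
#' @param tr repetition time in seconds.
#' @param signal_sd,noise_sd per-voxel latent signal and white-noise SD.
#' @param drift_amplitude amplitude of slow drift terms (per-voxel random
#'   weights on shared sub-1/128 Hz components).
#' @param nuisance_latent optional time-by-signal matrix of shared nuisance
#'   time courses (e.g. the latents behind the WM/CSF pools).
#' @param nuisance_gamma per-voxel coupling matrix (voxels x latents).
#' @param artifact_vols,artifact_sd volumes receiving an additive global
#'   glitch (e.g. motion spikes) and its SD in units of `noise_sd`.
#' @param switch_vols integer vector, see `loadings`.
#' @param voxel_ids optional voxel labels.
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return a [roi_ts()] object.
#' @export
generate_roi_run <- function(loadings, n_volumes, tr, signal_sd = 1,
                             noise_sd = 0.8, drift_amplitude = 0,
                             nuisance_latent = NULL, nuisance_gamma = NULL,
                             artifact_vols = integer(0), artifact_sd = 0,
                             switch_vols = integer(0), voxel_ids = NULL,
                             seed = NULL) {
  if (n_volumes < 2)
    stop_mvcsi("mvcsi_invalid", "field 'n_volumes' must be >= 2")
  if (is.matrix(loadings)) loadings <- list(loadings)
  n_vox <- nrow(loadings[[1]])
  k <- ncol(loadings[[1]])
  if (length(loadings) != length(switch_vols) + 1L)
    stop_mvcsi("mvcsi_invalid",
               "need one loading matrix per segment (switch_vols + 1)")
  with_seed(seed, {
    fac <- vapply(seq_len(k), function(j) smooth_signal(n_volumes, tr),
                  numeric(n_volumes))
    # scale so that a unit-norm loading column contributes signal_sd^2 / k
    # variance on average per voxel
    fac <- fac * signal_sd * sqrt(n_vox / k)
    bounds <- c(1L, as.integer(switch_vols), n_volumes + 1L)
    x <- matrix(0, n_volumes, n_vox)
    for (seg in seq_along(loadings)) {
      rows <- seq.int(bounds[seg], bounds[seg + 1L] - 1L)
      x[rows, ] <- fac[rows, , drop = FALSE] %*% t(loadings[[seg]])
    }
    if (drift_amplitude > 0) {
      dr <- drift_signals(n_volumes, tr)
      wdr <- matrix(rnorm(3 * n_vox, sd = drift_amplitude), 3, n_vox)
      x <- x + dr %*% wdr
    }
    if (!is.null(nuisance_latent) && !is.null(nuisance_gamma))
      x <- x + as.matrix(nuisance_latent) %*% t(as.matrix(nuisance_gamma))
    if (noise_sd > 0)
      x <- x + matrix(rnorm(n_volumes * n_vox, sd = noise_sd),
                      n_volumes, n_vox)
    if (length(artifact_vols) && artifact_sd > 0)
      x[artifact_vols, ] <- x[artifact_vols, ] +
        matrix(rnorm(length(artifact_vols) * n_vox,
                     sd = artifact_sd * max(noise_sd, 1e-3)),
               length(artifact_vols), n_vox)
    roi_ts(x, tr = tr, voxel_ids = voxel_ids)
  })
}

#' Generate synthetic head-motion parameters
#'
#' Slow random-walk trajectories on all six rigid-body axes plus occasional
#' sustained position steps ("spikes") of `spike_mag` mm, drawn per volume
#' with probability `spike_prob`. Under the default walk step sizes the
#' expected fraction of framewise-displacement exceedances of the 0.5 mm
#' scrubbing threshold is approximately `spike_prob`.
#'
#' @param n_volumes volumes in the run.
#' @param spike_prob per-volume probability of a position step.
#' @param spike_mag Euclidean size of the step in mm (> the 0.5 mm
#'   threshold by default).
#' @param walk_sd,walk_sd_rot random-walk step SDs (mm, rad).
#' @param seed optional seed.
#' @return a [motion_params()] matrix.
#' @export
generate_motion <- function(n_volumes, spike_prob = 0.02, spike_mag = 0.8,
                            walk_sd = 0.01, walk_sd_rot = 2e-4,
                            seed = NULL) {
  if (spike_prob < 0 || spike_prob > 1)
    stop_mvcsi("mvcsi_invalid", "field 'spike_prob' must lie in [0, 1]")
  with_seed(seed, {
    steps <- cbind(matrix(rnorm(3 * n_volumes, sd = walk_sd), n_volumes, 3),
                   matrix(rnorm(3 * n_volumes, sd = walk_sd_rot),
                          n_volumes, 3))
    steps[1, ] <- 0
    spike_at <- which(rbinom(n_volumes, 1, spike_prob) == 1 &
                        seq_len(n_volumes) > 1)
    for (t in spike_at) {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      steps[t, 1:3] <- steps[t, 1:3] + dir * spike_mag
    }
    motion_params(apply(steps, 2, cumsum))
  })
}
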