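test_that("detrending and high-pass filtering behave as a projection", {
  set.seed(101)
  # constant series vanish
  run <- roi_ts(matrix(5, 50, 3), tr = 2)
  out <- detrend_highpass(run)
  expect_lt(max(abs(out$data)), 1e-10)

  # slow sinusoid (period 256 s) almost fully removed at TR 2 s, 300 vols
  t_s <- (0:299) * 2
  slow <- sin(2 * pi * t_s / 256)
  fast <- sin(2 * pi * t_s / 32)
  run <- roi_ts(cbind(slow, fast), tr = 2)
  out <- detrend_highpass(run)
  expect_lt(sum(out$data[, 1]^2) / sum(slow^2), 0.01)
  expect_gt(sum(out$data[, 2]^2) / sum(fast^2), 0.99)

  # variance never increases, and filtering is idempotent
  run <- rand_run(120, 5, tr = 1)
  out <- detrend_highpass(run)
  expect_true(all(apply(out$data, 2, var) <= apply(run$data, 2, var)))
  out2 <- detrend_highpass(out)
  expect_equal(out2$data, out$data, tolerance = 1e-10)

  expect_error(detrend_highpass(rand_run(5, 2)), class = "mvcsi_invalid")
  expect_error(detrend_highpass(rand_run(50, 2), cutoff_hz = 1e-6),
               class = "mvcsi_invalid")
})

test_that("framewise displacement follows the Power convention", {
  zero <- matrix(0, 10, 6)
  expect_equal(compute_fd(zero), rep(0, 10), ignore_attr = TRUE)

  # transient 0.3 mm x-step at volume 5 (returns at volume 6): FD spikes
  # at the step and at the return
  m <- matrix(0, 10, 6); m[5, 1] <- 0.3
  fd <- compute_fd(m)
  expect_equal(as.numeric(fd[5]), 0.3)
  expect_equal(as.numeric(fd[6]), 0.3)
  expect_equal(sum(fd), 0.6)

  # sustained step: one exceedance only
  m <- matrix(0, 10, 6); m[5:10, 1] <- 0.3
  fd <- compute_fd(m)
  expect_equal(as.numeric(fd[5]), 0.3)
  expect_equal(sum(fd), 0.3)

  # sustained 0.01 rad rotation: 50 mm * 0.01 = 0.5 mm
  m <- matrix(0, 10, 6); m[3:10, 4] <- 0.01
  expect_equal(as.numeric(compute_fd(m)[3]), 0.5)

  expect_error(compute_fd(matrix(0, 5, 5)), class = "mvcsi_invalid")
})

test_that("scrubbing removes exceeding volumes plus successors", {
  fd <- c(0, .2, .6, .3, .2, .55, .1)
  run <- rand_run(7, 4)
  out <- censor_frames(run, fd, threshold_mm = 0.5)
  expect_equal(out$frame_index, c(1L, 2L, 5L))
  expect_equal(out$data, run$data[c(1, 2, 5), ])

  # all below threshold: identity
  out <- censor_frames(run, rep(0.1, 7))
  expect_equal(out$data, run$data)

  # exceedance at the last volume removes only that volume
  out <- censor_frames(run, c(rep(0, 6), 0.9))
  expect_equal(out$frame_index, 1:6)

  # all censored signals an unusable run
  expect_error(censor_frames(run, rep(1, 7)), class = "mvcsi_run_unusable")
})

test_that("down-sampling lands on original samples for integer TR ratios", {
  x <- matrix(rnorm(300 * 4), 300, 4)
  run <- roi_ts(x, tr = 1)
  out <- resample_to_tr(run, 2)
  expect_equal(nrow(out$data), 150)
  expect_equal(out$tr, 2)
  expect_equal(out$data, x[seq(1, 299, by = 2), ], ignore_attr = TRUE)

  const <- roi_ts(matrix(3, 100, 2), tr = 1)
  expect_true(all(resample_to_tr(const, 2.5)$data == 3))

  expect_error(resample_to_tr(run, 0.5), class = "mvcsi_invalid")
})

test_that("motion regressor expansion yields the 24 standard columns", {
  m <- matrix(0, 20, 6)
  expect_equal(dim(build_motion_regressors(m)), c(20L, 24L))
  expect_true(all(build_motion_regressors(m) == 0))

  m[, 2] <- seq_len(20) * 0.1  # linear ramp: constant derivative after row 1
  reg <- build_motion_regressors(m)
  expect_equal(unname(reg[2:20, "trans_y_mm_deriv"]), rep(0.1, 19))
  expect_equal(unname(reg[1, "trans_y_mm_deriv"]), 0)
  expect_equal(unname(reg[, "trans_y_mm_sq"]), (seq_len(20) * 0.1)^2)
})

test_that("tissue components are leading PCs with fixed sign and norm", {
  set.seed(55)
  # rank-1 WM pool: first component carries all variance
  base <- rnorm(60)
  wm <- outer(base, c(1, 2, 3, 4))
  csf <- matrix(rnorm(60 * 5), 60, 5)
  expect_warning(out <- extract_tissue_components(wm, csf, k = 3),
                 "rank")
  expect_true(isTRUE(attr(out, "rank_deficient")))
  pc1 <- out[, 1]
  expect_equal(abs(cor(pc1, base)), 1, tolerance = 1e-10)

  # orthogonal equal-variance signals split variance equally
  n <- 64
  # orthonormal columns built inside the mean-zero subspace, so they stay
  # exactly orthogonal after prcomp's centering
  base0 <- scale(matrix(rnorm(n * 4), n, 4), center = TRUE, scale = FALSE)
  tcs <- qr.Q(qr(base0))
  ev <- prcomp(tcs)$sdev^2
  expect_lt(diff(range(ev[1:4])) / mean(ev[1:4]), 1e-6)

  out <- extract_tissue_components(matrix(rnorm(60 * 8), 60, 8),
                                   matrix(rnorm(60 * 8), 60, 8), k = 3)
  expect_equal(ncol(out), 6)
  expect_equal(colnames(out),
               c("wm_pc1", "wm_pc2", "wm_pc3", "csf_pc1", "csf_pc2",
                 "csf_pc3"))
  # unit-norm scores, largest-magnitude loading positive
  expect_equal(colSums(out^2), rep(1, 6), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("nuisance regression residuals are orthogonal to regressors", {
  set.seed(77)
  run <- rand_run(80, 6)
  nuis <- matrix(rnorm(80 * 10), 80, 10)
  out <- regress_nuisance(run, nuis)
  expect_lt(max(abs(cor(out$data, nuis))), 1e-10)

  # voxel equal to a regressor is annihilated
  run2 <- run
  run2$data[, 1] <- nuis[, 3]
  out2 <- regress_nuisance(run2, nuis)
  expect_lt(max(abs(out2$data[, 1])), 1e-10)

  # empty nuisance set demeans
  out3 <- regress_nuisance(run, NULL)
  expect_equal(out3$data, scale(run$data, scale = FALSE),
               ignore_attr = TRUE)

  # collinear columns are dropped and named
  nuis_coll <- cbind(a = nuis[, 1], b = nuis[, 2], c = nuis[, 1] * 2)
  expect_message(out4 <- regress_nuisance(run, nuis_coll), "collinear")
  expect_equal(attr(out4, "dropped_regressors"), "c")
})

test_that("gray-matter selection uses a strict threshold", {
  run <- rand_run(30, 4)
  out <- select_voxels_gm(run, c(0.05, 0.10, 0.11, 0.9), threshold = 0.10)
  expect_equal(out$voxel_ids, c("v3", "v4"))
  expect_equal(select_voxels_gm(run, rep(1, 4))$data, run$data)
  expect_equal(select_voxels_gm(run, c(.2, .3, .4, .5),
                                threshold = 0)$data, run$data)
  expect_error(select_voxels_gm(run, rep(0.01, 4)),
               class = "mvcsi_roi_unusable")
  expect_error(select_voxels_gm(run, c(0.5, 0.5)), class = "mvcsi_invalid")
})

test_that("volume matching takes a centred window of the longer run", {
  a <- rand_run(10, 4)
  b <- rand_run(6, 4)
  m <- match_volumes(a, b, min_volumes = 5)
  expect_equal(m$a$frame_index, 3:8)   # 0-based positions 2..7
  expect_equal(m$b$data, b$data)

  m2 <- match_volumes(rand_run(7, 4), b, min_volumes = 5)
  expect_equal(m2$a$frame_index, 1:6)  # floor((7-6)/2) = 0

  same <- match_volumes(a, rand_run(10, 4), min_volumes = 5)
  expect_equal(nrow(same$a$data), 10)

  expect_error(match_volumes(a, b, min_volumes = 30),
               class = "mvcsi_pair_unusable")
  expect_error(match_volumes(a, rand_run(6, 4, tr = 2), min_volumes = 5),
               class = "mvcsi_invalid")
})

test_that("sphere ROI matches a brute-force lattice count", {
  m <- build_sphere_roi(c(0, 0, 0), radius_mm = 10, spacing_mm = 2)
  # independent enumeration over a generous lattice
  grid <- as.matrix(expand.grid(x = -10:10, y = -10:10, z = -10:10))
  inside <- rowSums((grid * 2)^2) <= 100
  expect_equal(nrow(m$coords), sum(inside))
  expect_equal(nrow(m$coords), 515)

  # symmetric under reflection about the centre
  expect_setequal(apply(m$coords, 1, paste, collapse = ","),
                  apply(-m$coords, 1, paste, collapse = ","))

  # radius below spacing keeps exactly the central voxel
  tiny <- build_sphere_roi(c(4, 4, 4), radius_mm = 1, spacing_mm = 2)
  expect_equal(unname(tiny$coords), matrix(c(2L, 2L, 2L), 1))

  expect_error(build_sphere_roi(c(1, 1, 1), radius_mm = 0.4,
                                spacing_mm = 2), class = "mvcsi_invalid")
})

test_that("coronal split partitions the mask at the middle slice", {
  coords <- as.matrix(expand.grid(x = 0:2, y = 10:19, z = 0:1))
  mask <- roi_mask(coords)
  sp <- split_mask_coronal(mask)
  expect_setequal(unique(sp$anterior$coords[, 2]), 15:19)
  expect_setequal(unique(sp$posterior$coords[, 2]), 10:14)
  # exhaustive and disjoint
  all_keys <- apply(coords, 1, paste, collapse = ",")
  part_keys <- c(apply(sp$anterior$coords, 1, paste, collapse = ","),
                 apply(sp$posterior$coords, 1, paste, collapse = ","))
  expect_setequal(all_keys, part_keys)
  expect_equal(length(part_keys), length(unique(part_keys)))

  single <- roi_mask(cbind(0:3, 5L, 0L))
  expect_error(split_mask_coronal(single), class = "mvcsi_invalid")
})

test_that("preprocess_run keeps exact volume accounting", {
  set.seed(31)
  run <- roi_ts(matrix(rnorm(200 * 20), 200, 20), tr = 1)
  motion <- generate_motion(200, spike_prob = 0.05, seed = 8)
  wm <- matrix(rnorm(200 * 8), 200, 8)
  csf <- matrix(rnorm(200 * 8), 200, 8)
  out <- preprocess_run(run, motion, wm, csf, gm_prob = runif(20, .2, 1))
  expect_equal(attr(out, "n_input_volumes"),
               nrow(out$data) + attr(out, "n_censored"))
  expect_true(attr(out, "censored_fraction") >= 0)
  # residuals orthogonal to the motion regressors on retained rows
  reg <- build_motion_regressors(motion)[out$frame_index, ]
  reg <- reg[, apply(reg, 2, sd) > 0]
  expect_lt(max(abs(cor(out$data, reg))), 1e-8)
})
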