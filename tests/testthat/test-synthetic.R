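small_cfg <- function(...) {
  synth_config(n_subjects = 2, rois = c(roiA = 30), n_factors = 6, ...)
}

test_that("config validation names the offending field", {
  expect_error(synth_config(n_subjects = 0), "n_subjects",
               class = "mvcsi_invalid")
  expect_error(synth_config(rho = c(early_late = 1.2, rs_pre_post = .5,
                                    task_rs_post = .5)),
               "rho", class = "mvcsi_invalid")
  expect_error(synth_config(spike_prob = -0.1), "spike_prob",
               class = "mvcsi_invalid")
  expect_error(synth_config(rois = c(30, 40)), "rois",
               class = "mvcsi_invalid")
})

test_that("identical config and seed reproduce the study bit for bit", {
  cfg <- small_cfg(seed = 99)
  s1 <- generate_experiment(cfg)
  s2 <- generate_experiment(cfg)
  expect_identical(s1, s2)
  s3 <- generate_experiment(small_cfg(seed = 100))
  expect_false(identical(s1$sessions, s3$sessions))
})

test_that("visit order is a wrapping Latin square over conditions", {
  d <- study_design(4)
  tab <- table(d$condition, d$visit)
  expect_true(all(tab == 1))
  d8 <- study_design(8)
  expect_true(all(table(d8$condition, d8$visit) == 2))
  # every subject sees each condition exactly once
  expect_true(all(table(d8$subject) == 4))
})

test_that("generated runs match the acquisition geometry", {
  s <- generate_experiment(small_cfg(seed = 7))
  ses <- s$sessions[["s01"]][["cSEQ"]]
  expect_equal(nrow(ses$rois$roiA$pre_rs$data), 300)
  expect_equal(ses$rois$roiA$pre_rs$tr, 1)
  expect_equal(nrow(ses$rois$roiA$post_rs$data), 300)
  expect_gte(nrow(ses$rois$roiA$task$data), 300)
  expect_equal(ses$rois$roiA$task$tr, 2)
  expect_equal(nrow(ses$motion$task), nrow(ses$rois$roiA$task$data))
  ann <- ses$rois$roiA$task$block_annotations
  expect_equal(sum(ann$phase == "practice"), 16)
  expect_true(all(diff(ann$start_vol) > 0))
})

test_that("rank-1 loadings give unit pairwise correlations", {
  run <- generate_roi_run(matrix(1, 20, 1), 50, 1, noise_sd = 0,
                          drift_amplitude = 0, seed = 3)
  cc <- cor(run$data)
  expect_equal(cc, matrix(1, 20, 20), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(generate_roi_run(matrix(1, 5, 1), 1, 1),
               class = "mvcsi_invalid")
})

test_that("orthogonal loading groups give near-zero cross correlations", {
  set.seed(42)
  w <- rbind(cbind(rnorm(15), 0), cbind(0, rnorm(15)))
  run <- generate_roi_run(w, 4000, 1, noise_sd = 0, drift_amplitude = 0,
                          seed = 4)
  cc <- cor(run$data)
  cross <- cc[1:15, 16:30]
  expect_lt(mean(abs(cross)), 0.1)  # Monte-Carlo tolerance, smooth signals
})

test_that("shared loadings raise MVCS similarity above independent ones", {
  set.seed(43)
  si_shared <- si_indep <- numeric(25)
  for (i in 1:25) {
    w <- mvcsi:::random_loadings(40, 6)
    a <- generate_roi_run(w, 120, 1)
    b <- generate_roi_run(w, 120, 1)
    c <- generate_roi_run(mvcsi:::random_loadings(40, 6), 120, 1)
    si_shared[i] <- similarity_index(compute_mvcs(a), compute_mvcs(b))
    si_indep[i] <- similarity_index(compute_mvcs(a), compute_mvcs(c))
  }
  expect_gt(mean(si_shared), mean(si_indep) + 0.2)
  expect_lt(abs(mean(si_indep)), 0.05)
})

test_that("motion spikes hit the scrubbing threshold at the right rate", {
  # no spikes, no walk: FD identically zero
  m0 <- generate_motion(100, spike_prob = 0, walk_sd = 0,
                        walk_sd_rot = 0, seed = 5)
  expect_true(all(compute_fd(m0) == 0))
  expect_identical(generate_motion(50, seed = 6),
                   generate_motion(50, seed = 6))

  frac <- vapply(1:100, function(i) {
    fd <- compute_fd(generate_motion(300, spike_prob = 0.05, seed = 1000 + i))
    mean(fd > 0.5)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.05), 0.02)
  expect_error(generate_motion(100, spike_prob = 2),
               class = "mvcsi_invalid")
})

test_that("behavioral generator follows the exponential learning model", {
  # zero amplitude: SEQ and RND share their RT distribution
  seq0 <- generate_behavior("SEQ", learning_amp_ms = 0, seed = 21)
  rnd0 <- generate_behavior("RND", learning_amp_ms = 0, seed = 21)
  expect_equal(seq0$rt_ms, rnd0$rt_ms, tolerance = 1e-12)

  # large rate: block 16 sits at the asymptote
  fast <- generate_behavior("SEQ", learning_rate = 5, seed = 22)
  bp <- block_performance(fast)
  expect_lt(abs(bp$mean_rt_correct[16] - 500), 25)
  expect_gt(bp$mean_rt_correct[1], 600)

  # rate recovery by exponential curve fit across seeds
  lam_hat <- vapply(1:60, function(i) {
    b <- generate_behavior("SEQ", seed = 3000 + i)
    bp <- block_performance(b)
    fit <- try(stats::nls(mean_rt_correct ~ A + B * exp(-l * (block - 1)),
                          data = bp,
                          start = list(A = 480, B = 120, l = 0.3)),
               silent = TRUE)
    if (inherits(fit, "try-error")) NA else coef(fit)[["l"]]
  }, numeric(1))
  expect_lt(abs(mean(lam_hat, na.rm = TRUE) - 0.35) / 0.35, 0.2)

  # SEQ sequence structure: 8-element cycle, six repeats per block
  sq <- generate_behavior("SEQ", seed = 23)
  expect_equal(sq$target_key[1:8], sq$target_key[9:16])
  expect_true(all(table(sq$target_key[sq$block == 1]) == 6))
  rnd <- generate_behavior("RND", seed = 24)
  expect_true(all(table(rnd$target_key[rnd$block == 1]) == 6))
})

test_that("block performance summarises correct presses only", {
  log <- data.frame(block = 1, press = 1:4, target_key = 1,
                    pressed_key = 1,
                    correct = c(TRUE, TRUE, FALSE, TRUE),
                    rt_ms = c(300, 400, 500, 200))
  bp <- block_performance(log)
  expect_equal(bp$mean_rt_correct, 300)
  expect_equal(bp$accuracy, 75)

  allc <- data.frame(block = 1, correct = rep(TRUE, 10), rt_ms = 250)
  expect_equal(block_performance(allc)$mean_rt_correct, 250)
  expect_equal(block_performance(allc)$accuracy, 100)

  none <- data.frame(block = 1, correct = rep(FALSE, 5), rt_ms = 250)
  bp0 <- block_performance(none)
  expect_true(is.na(bp0$mean_rt_correct))
  expect_equal(bp0$accuracy, 0)

  # accuracy ignores RT values; RT ignores incorrect presses
  log2 <- log; log2$rt_ms <- log$rt_ms * 10
  expect_equal(block_performance(log2)$accuracy, 75)
  log3 <- log; log3$rt_ms[3] <- 9999
  expect_equal(block_performance(log3)$mean_rt_correct, 300)
})

test_that("behavioral ground truth is recovered at the block-mean level", {
  # block-1 minus block-16 SEQ difference approximates B (1 - exp(-15 l))
  diffs <- vapply(1:40, function(i) {
    bp <- block_performance(generate_behavior("SEQ", seed = 5000 + i))
    bp$mean_rt_correct[1] - bp$mean_rt_correct[16]
  }, numeric(1))
  expected <- 150 * (1 - exp(-0.35 * 15))
  expect_lt(abs(mean(diffs) - expected), 15)
})
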