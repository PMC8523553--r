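# Dense-algebra REML objective, independent of the fitting code path:
# builds each subject's covariance block explicitly and uses solve() and
# determinant() instead of Cholesky whitening.
brute_neg2reml <- function(Sigma, X, y, subject, cell) {
  p <- ncol(X)
  XtWX <- matrix(0, p, p); XtWy <- numeric(p); ytWy <- 0; logdet <- 0
  for (s in unique(subject)) {
    r <- which(subject == s)
    Si <- Sigma[cell[r], cell[r], drop = FALSE]
    Wi <- solve(Si)
    logdet <- logdet + as.numeric(determinant(Si, logarithm = TRUE)$modulus)
    XtWX <- XtWX + t(X[r, , drop = FALSE]) %*% Wi %*% X[r, , drop = FALSE]
    XtWy <- XtWy + t(X[r, , drop = FALSE]) %*% Wi %*% y[r]
    ytWy <- ytWy + drop(t(y[r]) %*% Wi %*% y[r])
  }
  b <- solve(XtWX, XtWy)
  logdet + as.numeric(determinant(XtWX, logarithm = TRUE)$modulus) +
    ytWy - drop(crossprod(XtWy, b))
}

paired_wide <- function(d) {
  reshape(d[, c("subject", "condition", "si")], idvar = "subject",
          timevar = "condition", direction = "wide")
}

test_that("two-condition fit reproduces the paired t test exactly", {
  for (i in 1:10) {
    n <- sample(8:25, 1)
    d <- simulate_si_study(n_subjects = n, seed = 400 + i)
    d <- d[d$condition %in% c("cSEQ", "iRND"), ]
    fit <- rm_lmm(si ~ condition, d, within = "condition")
    w <- paired_wide(d)
    tt <- t.test(w[[2]], w[[3]], paired = TRUE)
    expect_equal(fit$anova$F, unname(tt$statistic)^2, tolerance = 1e-6)
    expect_equal(fit$anova$df2, n - 1, tolerance = 1e-6)
    expect_equal(fit$anova$p, tt$p.value, tolerance = 1e-6)
  }
})

test_that("unstructured fit matches the nlme::gls oracle", {
  skip_if_not_installed("nlme")
  d <- simulate_si_study(n_subjects = 15, seed = 88,
                         effects = c(task = 0.5, stimulation = 0,
                                     interaction = 0.3))
  fit <- fit_lmm_si(d)
  d$condition <- interaction(d$stimulation, d$task, sep = "_")
  d$visit <- factor(d$visit)
  d$stimulation <- factor(d$stimulation)
  d$task <- factor(d$task)
  contrasts(d$visit) <- contr.sum(4)
  contrasts(d$stimulation) <- contr.sum(2)
  contrasts(d$task) <- contr.sum(2)
  g <- nlme::gls(si ~ visit + stimulation * task, data = d,
                 correlation = nlme::corSymm(
                   form = ~ as.integer(condition) | subject),
                 weights = nlme::varIdent(form = ~ 1 | condition),
                 method = "REML",
                 control = nlme::glsControl(tolerance = 1e-12))
  expect_equal(unname(fit$beta), unname(coef(g)), tolerance = 1e-5)
  expect_equal(unname(sqrt(diag(fit$vcov_beta))),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)
  av <- anova(g, type = "marginal")
  expect_equal(fit$anova$F, av$`F-value`[-1], tolerance = 1e-4)
})

test_that("structured REML objective equals dense brute-force algebra", {
  # unstructured, with a missing cell
  d <- simulate_si_study(n_subjects = 10, seed = 31,
                         missing_cells = data.frame(subject = "s03",
                                                    condition = "iRND"))
  fit <- fit_lmm_si(d)
  expect_equal(fit$neg2_reml,
               brute_neg2reml(fit$Sigma, fit$X, fit$y, fit$subject_index,
                              fit$cell_index),
               tolerance = 1e-8)

  # Kronecker structure on a small block design
  beh <- make_behavior_design(8, seed = 32, effects = list(n_blocks = 4))
  fitk <- fit_lmm_behavior(beh)
  expect_equal(fitk$neg2_reml,
               brute_neg2reml(fitk$Sigma, fitk$X, fitk$y,
                              fitk$subject_index, fitk$cell_index),
               tolerance = 1e-8)
  # the Kronecker covariance really is Sigma_c (x) CS
  m_b <- 4
  R <- fitk$Sigma[1:m_b, 1:m_b] / fitk$Sigma[1, 1]
  expect_equal(diag(R), rep(1, m_b), ignore_attr = TRUE, tolerance = 1e-8)
  off <- R[upper.tri(R)]
  expect_lt(diff(range(off)), 1e-8)
  # no better optimum reachable from the reported one
  st <- mvcsi:::struct_kron_cs(4, m_b)
  refit <- optim(fitk$theta, function(th)
    brute_neg2reml(st$Sigma(th), fitk$X, fitk$y, fitk$subject_index,
                   fitk$cell_index), method = "Nelder-Mead",
    control = list(maxit = 400))
  expect_gt(refit$value, fitk$neg2_reml - 1e-3)
})

test_that("balanced complete data give OLS fixed effects under any structure", {
  d <- simulate_si_study(n_subjects = 12, seed = 33,
                         effects = c(task = 1, stimulation = 0.5,
                                     interaction = 0))
  d$visit <- NULL
  fit <- fit_lmm_si(d)
  d$stimulation <- factor(d$stimulation); d$task <- factor(d$task)
  contrasts(d$stimulation) <- contr.sum(2)
  contrasts(d$task) <- contr.sum(2)
  ols <- lm(si ~ stimulation * task, d)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-8)
})

test_that("constant response yields a flagged degenerate fit with zero F", {
  d <- simulate_si_study(n_subjects = 8, seed = 34)
  d$si <- 0.42
  fit <- fit_lmm_si(d)
  expect_true(fit$degenerate)
  expect_true(all(fit$anova$F < 1e-8))
})

test_that("Satterthwaite df respond to covariance-parameter uncertainty", {
  d <- simulate_si_study(n_subjects = 20, seed = 35)
  d2 <- d[d$condition %in% c("cSEQ", "cRND"), ]
  fit_big <- rm_lmm(si ~ condition, d2, within = "condition")
  d3 <- d2[d2$subject %in% unique(d2$subject)[1:8], ]
  fit_small <- rm_lmm(si ~ condition, d3, within = "condition")
  c_task <- c(0, 1)
  expect_equal(satterthwaite_df(fit_big, c_task), 19, tolerance = 1e-6)
  expect_equal(satterthwaite_df(fit_small, c_task), 7, tolerance = 1e-6)
  expect_lt(satterthwaite_df(fit_small, c_task),
            satterthwaite_df(fit_big, c_task))
})

test_that("follow-up contrasts behave as single-df cell comparisons", {
  d <- simulate_si_study(n_subjects = 14, seed = 36,
                         effects = c(task = 1.2, stimulation = 0,
                                     interaction = 0))
  fit <- fit_lmm_si(d)
  # a cell against itself is exactly null
  same <- followup_contrast(fit, a = list(stimulation = "cTBS",
                                          task = "SEQ"),
                            b = list(stimulation = "cTBS", task = "SEQ"))
  expect_equal(same$F, 0)
  expect_equal(same$estimate, 0)

  # in the two-condition sub-design the contrast is the omnibus test
  d2 <- d[d$condition %in% c("cSEQ", "cRND"), ]
  fit2 <- rm_lmm(si ~ condition, d2, within = "condition")
  fu <- followup_contrast(fit2, a = list(condition = "cSEQ"),
                          b = list(condition = "cRND"))
  expect_equal(fu$F, fit2$anova$F, tolerance = 1e-8)
  expect_equal(fu$df2, fit2$anova$df2, tolerance = 1e-8)

  expect_error(followup_contrast(fit, a = list(task = "XYZ"),
                                 b = list(task = "RND")),
               class = "mvcsi_invalid")
})

test_that("behavior model detects the learning-curve interaction", {
  beh <- make_behavior_design(8, seed = 37)
  fit <- fit_lmm_behavior(beh)
  expect_equal(fit$convergence, 0)
  tab <- fit$anova
  expect_lt(tab$p[tab$term == "task:block"], 0.001)
  expect_lt(tab$p[tab$term == "block"], 0.001)
  expect_gt(tab$p[tab$term == "stimulation"], 0.01)
  # estimated block-to-block correlation is substantial (subject effects)
  expect_gt(fit$Sigma[1, 2] / fit$Sigma[1, 1], 0.1)
})

test_that("single-block behavioral design reduces to the condition model", {
  beh <- make_behavior_design(9, seed = 38, effects = list(n_blocks = 1))
  fitb <- fit_lmm_behavior(beh)
  si_like <- beh
  si_like$si <- si_like$mean_rt_correct
  fits <- fit_lmm_si(si_like)
  expect_equal(fitb$anova$F, fits$anova$F, tolerance = 1e-6)
  expect_equal(fitb$anova$df2, fits$anova$df2, tolerance = 1e-4)
})

test_that("BH adjustment matches the hand step-up rule", {
  out <- fdr_bh(c(a = 0.01, b = 0.02, c = 0.03, d = 0.04), q = 0.05)
  expect_true(all(out$significant))
  expect_equal(out$p_fdr, c(0.04, 0.04, 0.04, 0.04))

  out1 <- fdr_bh(c(x = 1, y = 1, z = 1))
  expect_false(any(out1$significant))
  expect_equal(out1$p_fdr, rep(1, 3))

  expect_equal(fdr_bh(c(k = 0.03))$p_fdr, 0.03)
  expect_true(fdr_bh(c(k = 0.03))$significant)
  expect_equal(nrow(fdr_bh(numeric(0))), 0)
  expect_error(fdr_bh(c(0.5, 0)), class = "mvcsi_invalid")

  set.seed(39)
  for (i in 1:25) {
    p <- runif(4)
    got <- fdr_bh(p, q = 0.05)
    want <- brute_bh(p, q = 0.05)
    expect_identical(got$p_fdr, want$adj)
    expect_identical(got$significant, want$reject)
  }
})

test_that("REML fit never ends above its starting objective", {
  for (i in 1:5) {
    d <- simulate_si_study(n_subjects = 10, seed = 500 + i)
    fit <- fit_lmm_si(d)
    st <- mvcsi:::struct_un(4)
    theta0 <- mvcsi:::lmm_start(
      st, "unstructured", fit$X, fit$y,
      split(seq_along(fit$y), fit$subject_index),
      split(fit$cell_index, fit$subject_index), 4)
    start_val <- brute_neg2reml(st$Sigma(theta0), fit$X, fit$y,
                                fit$subject_index, fit$cell_index)
    expect_lte(fit$neg2_reml, start_val + 1e-8)
  }
})
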