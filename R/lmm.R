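# Repeated-measures linear mixed models by REML with structured
# within-subject covariance, Type-III F tests under sum-to-zero coding,
# and Satterthwaite denominator degrees of freedom.
#
# Model: y_i = X_i beta + e_i per subject i, e_i ~ N(0, Sigma[cells_i]),
# subjects independent, Sigma a structured covariance over within-subject
# cells. Two structures are provided:
#   * unstructured: fully parameterised m x m covariance (log-Cholesky);
#   * kronecker_cs: unstructured(conditions) (x) compound-symmetry
#     correlation(blocks), the compound-symmetry block in correlation form
#     (unit diagonal) so all scale lives in the unstructured factor; its
#     correlation is mapped to an unconstrained parameter by a scaled
#     logistic transform.
# Both parameterisations keep the implied covariance positive definite by
# construction, so the quasi-Newton optimiser runs unconstrained.

## ---- covariance structures ----------------------------------------------

# Unstructured m x m covariance via log-Cholesky: theta holds the lower
# triangle of L column-major, diagonal entries on log scale; Sigma = L L'.
struct_un <- function(m) {
  idx <- which(lower.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  npar <- nrow(idx)
  is_diag <- idx[, 1] == idx[, 2]
  build_L <- function(theta) {
    L <- matrix(0, m, m)
    v <- theta
    v[is_diag] <- exp(theta[is_diag])
    L[idx] <- v
    L
  }
  list(
    m = m, npar = npar,
    Sigma = function(theta) tcrossprod(build_L(theta)),
    dSigma = function(theta) {
      L <- build_L(theta)
      lapply(seq_len(npar), function(p) {
        E <- matrix(0, m, m)
        E[idx[p, 1], idx[p, 2]] <- if (is_diag[p]) L[idx[p, 1], idx[p, 2]]
          else 1
        E %*% t(L) + L %*% t(E)
      })
    },
    init = function(S) {
      S <- pd_floor(S)
      L <- t(chol(S))
      th <- L[idx]
      th[is_diag] <- log(pmax(diag(L), 1e-8))
      th
    })
}

# Kronecker product: unstructured over m_c conditions (x) compound-symmetry
# correlation over m_b blocks. Cell index = (condition - 1) * m_b + block.
struct_kron_cs <- function(m_c, m_b) {
  un <- struct_un(m_c)
  lo <- -1 / (m_b - 1) + 1e-3
  hi <- 1 - 1e-3
  rho_of <- function(z) lo + (hi - lo) / (1 + exp(-z))
  drho_of <- function(z) {
    p <- 1 / (1 + exp(-z))
    (hi - lo) * p * (1 - p)
  }
  J <- matrix(1, m_b, m_b)
  I_b <- diag(m_b)
  list(
    m = m_c * m_b, npar = un$npar + 1L, m_c = m_c, m_b = m_b,
    rho = rho_of,
    Sigma = function(theta) {
      R <- rho_of(theta[un$npar + 1L]) * (J - I_b) + I_b
      kronecker(un$Sigma(theta[seq_len(un$npar)]), R)
    },
    dSigma = function(theta) {
      z <- theta[un$npar + 1L]
      R <- rho_of(z) * (J - I_b) + I_b
      dS_c <- un$dSigma(theta[seq_len(un$npar)])
      c(lapply(dS_c, function(D) kronecker(D, R)),
        list(kronecker(un$Sigma(theta[seq_len(un$npar)]),
                       (J - I_b) * drho_of(z))))
    },
    init = function(S_c, rho0) {
      rho0 <- min(max(rho0, lo + 0.02), hi - 0.02)
      c(un$init(S_c), log((rho0 - lo) / (hi - rho0)))
    })
}

# Floor eigenvalues so a (near-)singular covariance estimate still yields a
# usable Cholesky start.
pd_floor <- function(S, rel = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  floor_val <- max(mean(diag(S)), 1e-12) * rel
  e$vectors %*% (pmax(e$values, floor_val) * t(e$vectors))
}

ginv_sym <- function(A, tol = 1e-10) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), 1e-300)
  if (!any(pos)) return(matrix(0, nrow(A), ncol(A)))
  e$vectors[, pos, drop = FALSE] %*%
    ((1 / e$values[pos]) * t(e$vectors[, pos, drop = FALSE]))
}

## ---- model assembly ------------------------------------------------------

#' Fit a repeated-measures linear mixed model
#'
#' REML fit of a fixed-effects model with correlated within-subject errors.
#' Every factor in the fixed-effects formula is coded sum-to-zero and each
#' fixed-effect term is tested with a Type-III Wald F statistic whose
#' denominator degrees of freedom come from the Satterthwaite
#' approximation (multi-df terms combine per-contrast df by the standard
#' harmonic rule). Subjects with incomplete cells are retained with their
#' available rows; rows with missing response are deleted.
#'
#' @param fixed model formula for the fixed effects, e.g.
#'   `si ~ visit + stimulation * task`.
#' @param data long-format data frame.
#' @param subject name of the subject identifier column.
#' @param within name(s) of the repeated-measures cell column(s): one
#'   column for `cov_type = "unstructured"`; for `"kronecker_cs"` two
#'   columns, the condition factor (unstructured part) then the block
#'   factor (compound-symmetry part).
#' @param cov_type within-subject covariance structure.
#' @param control list: `reltol`, `maxit` for the BFGS optimiser.
#' @return object of class `rm_lmm` with components `anova` (term, F,
#'   df1, df2, p), `beta`, `vcov_beta`, `Sigma` (fitted within-subject
#'   covariance), `theta`, `vcov_theta`, `logreml` (-2 restricted
#'   log-likelihood up to a constant), `convergence`, and the internals
#'   needed by [followup_contrast()] and [satterthwaite_df()].
#' @export
rm_lmm <- function(fixed, data, subject = "subject", within = "condition",
                   cov_type = c("unstructured", "kronecker_cs"),
                   control = list()) {
  cov_type <- match.arg(cov_type)
  ctrl <- modifyList(list(reltol = 1e-12, maxit = 500), control)
  data <- as.data.frame(data)
  resp <- all.vars(fixed)[1]
  used <- unique(c(all.vars(fixed), subject, within))
  miss <- setdiff(used, names(data))
  if (length(miss))
    stop_mvcsi("mvcsi_invalid", "columns not in data: %s",
               paste(miss, collapse = ", "))
  data <- data[complete.cases(data[, used, drop = FALSE]), , drop = FALSE]
  if (nrow(data) == 0L) stop_mvcsi("mvcsi_invalid", "no complete rows")

  # sum-to-zero coding for every factor-like fixed-effect variable
  for (v in setdiff(all.vars(fixed)[-1], resp)) {
    if (!is.numeric(data[[v]]) || v %in% within) {
      data[[v]] <- factor(data[[v]])
      stats::contrasts(data[[v]]) <- stats::contr.sum(nlevels(data[[v]]))
    }
  }
  for (v in within)
    if (!is.factor(data[[v]])) data[[v]] <- factor(data[[v]])

  # cell index within subject
  if (cov_type == "unstructured") {
    if (length(within) != 1L)
      stop_mvcsi("mvcsi_invalid", "'within' must name one column")
    cell <- as.integer(data[[within]])
    m <- nlevels(data[[within]])
    st <- struct_un(m)
    cell_labels <- levels(data[[within]])
  } else {
    if (length(within) != 2L)
      stop_mvcsi("mvcsi_invalid",
                 "'within' must name (condition, block) columns")
    m_c <- nlevels(data[[within[1]]])
    m_b <- nlevels(data[[within[2]]])
    cell <- (as.integer(data[[within[1]]]) - 1L) * m_b +
      as.integer(data[[within[2]]])
    m <- m_c * m_b
    st <- struct_kron_cs(m_c, m_b)
    cell_labels <- paste(rep(levels(data[[within[1]]]), each = m_b),
                         rep(levels(data[[within[2]]]), m_c), sep = ".")
  }
  subj <- factor(data[[subject]])
  if (anyDuplicated(paste(subj, cell)))
    stop_mvcsi("mvcsi_invalid", "duplicated subject x cell rows")

  trm <- terms(fixed, data = data)
  mf <- stats::model.frame(trm, data)
  X <- model.matrix(trm, mf)
  y <- stats::model.response(mf)
  asg <- attr(X, "assign")
  # drop rank-deficient fixed-effect columns (e.g. visit with < 4 levels)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    X <- X[, sort(keep), drop = FALSE]
    asg <- asg[sort(keep)]
  }
  p <- ncol(X)

  # order rows within subject by cell; group subjects by cell pattern
  ord <- order(subj, cell)
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  subj <- subj[ord]; cell <- cell[ord]
  sub_rows <- split(seq_along(y), subj)
  sub_cells <- lapply(sub_rows, function(r) cell[r])
  patterns <- split(seq_along(sub_rows),
                    vapply(sub_cells, function(cs)
                      paste(cs, collapse = ","), character(1)))

  degenerate <- isTRUE(stats::var(y) < 1e-24 * max(1, mean(y)^2))

  neg2_reml <- function(theta, want = "value") {
    Sigma <- st$Sigma(theta)
    XtWX <- matrix(0, p, p); XtWy <- numeric(p); ytWy <- 0; logdet <- 0
    pat_chol <- list()
    for (pn in names(patterns)) {
      cells_p <- sub_cells[[patterns[[pn]][1]]]
      Sp <- Sigma[cells_p, cells_p, drop = FALSE]
      ch <- tryCatch(chol(Sp), error = function(e) NULL)
      if (is.null(ch)) return(if (want == "value") 1e10 else NULL)
      pat_chol[[pn]] <- ch
      ld <- 2 * sum(log(diag(ch)))
      for (si in patterns[[pn]]) {
        r <- sub_rows[[si]]
        Zi <- backsolve(ch, cbind(y[r], X[r, , drop = FALSE]),
                        transpose = TRUE)
        XtWX <- XtWX + crossprod(Zi[, -1, drop = FALSE])
        XtWy <- XtWy + crossprod(Zi[, -1, drop = FALSE], Zi[, 1])
        ytWy <- ytWy + sum(Zi[, 1]^2)
        logdet <- logdet + ld
      }
    }
    chX <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(chX)) return(if (want == "value") 1e10 else NULL)
    beta <- backsolve(chX, backsolve(chX, XtWy, transpose = TRUE))
    rss <- ytWy - sum(XtWy * beta)
    val <- logdet + 2 * sum(log(diag(chX))) + rss
    if (want == "value") return(val)
    list(value = val, beta = beta, XtWX = XtWX, chX = chX,
         pat_chol = pat_chol, Sigma = Sigma)
  }

  # analytic REML score: d(-2 l_R)/d theta_j = tr(P V_j) - (Py)' V_j (Py)
  neg2_reml_grad <- function(theta) {
    fit <- neg2_reml(theta, want = "full")
    if (is.null(fit)) return(rep(0, st$npar))
    dS <- st$dSigma(theta)
    Phi <- chol2inv(fit$chX)
    grad <- numeric(st$npar)
    Tj <- vector("list", st$npar)
    for (j in seq_len(st$npar)) Tj[[j]] <- matrix(0, p, p)
    trWV <- numeric(st$npar)
    for (pn in names(patterns)) {
      cells_p <- sub_cells[[patterns[[pn]][1]]]
      W <- chol2inv(fit$pat_chol[[pn]])
      n_sub <- length(patterns[[pn]])
      for (j in seq_len(st$npar)) {
        Vj <- dS[[j]][cells_p, cells_p, drop = FALSE]
        A <- W %*% Vj
        trWV[j] <- trWV[j] + n_sub * sum(diag(A))
        G <- A %*% W
        for (si in patterns[[pn]]) {
          r <- sub_rows[[si]]
          Xi <- X[r, , drop = FALSE]
          Tj[[j]] <- Tj[[j]] + crossprod(Xi, G %*% Xi)
          Pyi <- W %*% (y[r] - Xi %*% fit$beta)
          grad[j] <- grad[j] - sum(Pyi * (Vj %*% Pyi))
        }
      }
    }
    for (j in seq_len(st$npar))
      grad[j] <- grad[j] + trWV[j] - sum(Phi * Tj[[j]])
    grad
  }

  theta0 <- lmm_start(st, cov_type, X, y, sub_rows, sub_cells, m)
  if (degenerate) {
    opt <- list(par = theta0, value = neg2_reml(theta0), convergence = 0L)
  } else {
    opt <- optim(theta0, neg2_reml, gr = neg2_reml_grad, method = "BFGS",
                 control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
    if (opt$convergence != 0) {
      opt2 <- optim(opt$par, neg2_reml, method = "Nelder-Mead",
                    control = list(maxit = 2000))
      opt3 <- optim(opt2$par, neg2_reml, gr = neg2_reml_grad,
                    method = "BFGS",
                    control = list(maxit = ctrl$maxit,
                                   reltol = ctrl$reltol))
      if (opt3$value <= opt$value) opt <- opt3
    }
  }
  theta <- opt$par
  fit <- neg2_reml(theta, want = "full")
  if (is.null(fit)) {
    # the optimum drifted into numerical singularity; fall back to the
    # best evaluable iterate (the starting estimate) and flag it
    theta <- theta0
    fit <- neg2_reml(theta, want = "full")
    opt$convergence <- 52L
    if (is.null(fit))
      stop_mvcsi("mvcsi_nonconvergence", "REML fit failed at the optimum")
  }
  Phi <- chol2inv(fit$chX)

  # Satterthwaite ingredients at the optimum: T_j = X'W V_j W X and the
  # expected REML information I_jk = 0.5 tr(P V_j P V_k).
  dS <- st$dSigma(theta)
  npar <- st$npar
  Tj <- lapply(seq_len(npar), function(j) matrix(0, p, p))
  I_R <- matrix(0, npar, npar)
  trWVWV <- matrix(0, npar, npar)
  Sjk <- array(0, c(p, p, npar * (npar + 1) / 2))
  jk_index <- function(j, k) {
    if (j > k) { tmp <- j; j <- k; k <- tmp }
    (k - 1) * k / 2 + j
  }
  for (pn in names(patterns)) {
    cells_p <- sub_cells[[patterns[[pn]][1]]]
    W <- chol2inv(fit$pat_chol[[pn]])
    n_sub <- length(patterns[[pn]])
    A <- lapply(dS, function(D) W %*% D[cells_p, cells_p, drop = FALSE])
    G <- lapply(A, function(a) a %*% W)
    for (j in seq_len(npar)) {
      for (si in patterns[[pn]]) {
        r <- sub_rows[[si]]
        Xi <- X[r, , drop = FALSE]
        Tj[[j]] <- Tj[[j]] + crossprod(Xi, G[[j]] %*% Xi)
      }
      for (k in j:npar) {
        trWVWV[j, k] <- trWVWV[j, k] + n_sub * sum(A[[j]] * t(A[[k]]))
        Hjk <- A[[j]] %*% G[[k]]
        ix <- jk_index(j, k)
        for (si in patterns[[pn]]) {
          r <- sub_rows[[si]]
          Xi <- X[r, , drop = FALSE]
          Sjk[, , ix] <- Sjk[, , ix] + crossprod(Xi, Hjk %*% Xi)
        }
      }
    }
  }
  for (j in seq_len(npar)) for (k in j:npar) {
    ix <- jk_index(j, k)
    val <- 0.5 * (trWVWV[j, k] - 2 * sum(Phi * Sjk[, , ix]) +
                    sum((Phi %*% Tj[[j]]) * t(Phi %*% Tj[[k]])))
    I_R[j, k] <- I_R[k, j] <- val
  }
  vcov_theta <- tryCatch(solve(I_R), error = function(e) ginv_sym(I_R))

  obj <- structure(list(
    beta = drop(fit$beta), vcov_beta = Phi, Sigma = fit$Sigma,
    theta = theta, vcov_theta = vcov_theta, Tj = Tj,
    logreml = -0.5 * opt$value, neg2_reml = opt$value,
    convergence = opt$convergence, degenerate = degenerate,
    cov_type = cov_type, cell_labels = cell_labels,
    n_subjects = length(sub_rows), n_obs = length(y),
    X = X, y = y, subject_index = subj, cell_index = cell,
    assign = asg, terms = trm,
    xlevels = stats::.getXlevels(trm, mf),
    contrasts = attr(X, "contrasts"),
    coef_names = colnames(X), within = within, call = match.call()),
    class = "rm_lmm")
  obj$anova <- type3_table(obj)
  obj
}

# Starting values from OLS residual covariance over cells.
lmm_start <- function(st, cov_type, X, y, sub_rows, sub_cells, m) {
  beta0 <- qr.coef(qr(X), y)
  beta0[is.na(beta0)] <- 0
  res <- y - X %*% beta0
  if (cov_type == "unstructured") {
    R <- matrix(NA_real_, length(sub_rows), m)
    for (i in seq_along(sub_rows)) R[i, sub_cells[[i]]] <- res[sub_rows[[i]]]
    S <- cov(R, use = "pairwise.complete.obs")
    S[is.na(S)] <- 0
    diag(S)[diag(S) <= 0 | is.na(diag(S))] <- max(stats::var(res), 1e-8)
    st$init(S)
  } else {
    m_b <- st$m_b; m_c <- st$m_c
    R <- matrix(NA_real_, length(sub_rows) * m_b, m_c)
    rho_num <- 0; rho_den <- 0
    for (i in seq_along(sub_rows)) {
      cells <- sub_cells[[i]]
      cnd <- (cells - 1L) %/% m_b + 1L
      blk <- (cells - 1L) %% m_b + 1L
      R[cbind((i - 1L) * m_b + blk, cnd)] <- res[sub_rows[[i]]]
      for (cc in unique(cnd)) {
        v <- res[sub_rows[[i]]][cnd == cc]
        if (length(v) > 1) {
          rho_num <- rho_num + (sum(v)^2 - sum(v^2))
          rho_den <- rho_den + sum(v^2) * (length(v) - 1)
        }
      }
    }
    S_c <- cov(R, use = "pairwise.complete.obs")
    S_c[is.na(S_c)] <- 0
    diag(S_c)[diag(S_c) <= 0 | is.na(diag(S_c))] <-
      max(stats::var(res), 1e-8)
    rho0 <- if (rho_den > 0) rho_num / rho_den else 0.1
    st$init(S_c, rho0)
  }
}

## ---- inference -----------------------------------------------------------

# Type-III Wald F table: under sum-to-zero coding, each term is tested by
# the joint nullity of its own coefficients.
type3_table <- function(fit) {
  labels <- attr(fit$terms, "term.labels")
  rows <- lapply(seq_along(labels), function(tn) {
    sel <- which(fit$assign == tn)
    if (!length(sel))
      return(data.frame(term = labels[tn], df1 = 0, df2 = NA, F = NA,
                        p = NA))
    L <- matrix(0, length(sel), length(fit$beta))
    L[cbind(seq_along(sel), sel)] <- 1
    ct <- contrast_F(fit, L)
    data.frame(term = labels[tn], df1 = ct$df1, df2 = ct$df2, F = ct$F,
               p = ct$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Wald F with Satterthwaite denominator df for a contrast matrix L
# (q x p). Multi-df terms: eigen-decompose L Phi L', get one Satterthwaite
# df per orthogonal contrast, combine by the harmonic rule
# nu = 2 E / (E - q), E = sum nu_m / (nu_m - 2).
contrast_F <- function(fit, L) {
  L <- matrix(L, ncol = length(fit$beta))
  q <- nrow(L)
  M <- L %*% fit$vcov_beta %*% t(L)
  Minv <- tryCatch(solve(M), error = function(e) ginv_sym(M))
  est <- drop(L %*% fit$beta)
  Fval <- drop(crossprod(est, Minv %*% est)) / q
  if (!is.finite(Fval) || Fval < 0) Fval <- 0
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  nus <- vapply(seq_len(q), function(mi) {
    l <- drop(crossprod(e$vectors[, mi], L))
    satterthwaite_df(fit, l)
  }, numeric(1))
  if (q == 1L) {
    df2 <- nus[1]
  } else {
    ok <- nus > 2
    E <- sum(nus[ok] / (nus[ok] - 2))
    df2 <- if (E > q) 2 * E / (E - q) else min(nus)
  }
  p <- if (is.finite(df2) && df2 > 0) pf(Fval, q, df2, lower.tail = FALSE)
    else NA_real_
  list(F = Fval, df1 = q, df2 = df2, p = p, estimate = est)
}

#' Satterthwaite denominator degrees of freedom for a contrast
#'
#' For a single contrast `c` of the fixed effects,
#' `nu = 2 (c' Phi c)^2 / (g' A g)` where `Phi` is the fixed-effect
#' covariance, `g` the gradient of `c' Phi(theta) c` in the covariance
#' parameters at the REML estimate, and `A` the inverse expected REML
#' information. The gradient is analytic:
#' `g_j = c' Phi T_j Phi c` with `T_j = X' V^-1 (dV/dtheta_j) V^-1 X`.
#'
#' @param fit an [rm_lmm()] object.
#' @param contrast numeric vector of length `length(fit$beta)`.
#' @return the approximate denominator df (a positive scalar).
#' @export
satterthwaite_df <- function(fit, contrast) {
  stopifnot(inherits(fit, "rm_lmm"))
  cvec <- as.numeric(contrast)
  if (length(cvec) != length(fit$beta))
    stop_mvcsi("mvcsi_invalid", "contrast length must be %d",
               length(fit$beta))
  f <- drop(crossprod(cvec, fit$vcov_beta %*% cvec))
  if (f <= 0) return(fit$n_obs - length(fit$beta))  # null contrast
  Phic <- fit$vcov_beta %*% cvec
  g <- vapply(fit$Tj, function(T) drop(crossprod(Phic, T %*% Phic)),
              numeric(1))
  denom <- drop(crossprod(g, fit$vcov_theta %*% g))
  if (!is.finite(denom) || denom <= 0) {
    warning("non-finite Satterthwaite denominator; using residual df")
    return(fit$n_obs - length(fit$beta))
  }
  2 * f^2 / denom
}

#' Follow-up contrast between two design cells
#'
#' Single-df F test of the difference between the model-implied means of
#' two cells (e.g. two stimulation-by-task conditions), evaluated at the
#' average of all factors not named in the cells (with sum-to-zero coding
#' this marginalises e.g. the visit factor). Satterthwaite df.
#'
#' @param fit an [rm_lmm()] object.
#' @param a,b named lists giving the factor levels defining each cell,
#'   e.g. `list(stimulation = "cTBS", task = "SEQ")`.
#' @return data.frame row with `estimate` (mean a - mean b), `F`, `df1`,
#'   `df2`, `p`.
#' @export
followup_contrast <- function(fit, a, b) {
  stopifnot(inherits(fit, "rm_lmm"))
  xa <- cell_row(fit, a)
  xb <- cell_row(fit, b)
  cvec <- xa - xb
  ct <- contrast_F(fit, matrix(cvec, 1))
  data.frame(estimate = ct$estimate, F = ct$F, df1 = 1, df2 = ct$df2,
             p = ct$p)
}

# Model-matrix row of a cell, averaged over unspecified factors.
cell_row <- function(fit, cell) {
  vars <- names(fit$xlevels)
  miss <- setdiff(names(cell), vars)
  if (length(miss))
    stop_mvcsi("mvcsi_invalid", "unknown cell factor(s): %s",
               paste(miss, collapse = ", "))
  for (v in names(cell))
    if (!cell[[v]] %in% fit$xlevels[[v]])
      stop_mvcsi("mvcsi_invalid", "level '%s' absent from factor '%s'",
                 cell[[v]], v)
  free <- setdiff(vars, names(cell))
  grid <- expand.grid(c(lapply(free, function(v) fit$xlevels[[v]]),
                        lapply(names(cell), function(v) cell[[v]])),
                      stringsAsFactors = FALSE)
  names(grid) <- c(free, names(cell))
  for (v in vars) {
    grid[[v]] <- factor(grid[[v]], levels = fit$xlevels[[v]])
    stats::contrasts(grid[[v]]) <- stats::contr.sum(nlevels(grid[[v]]))
  }
  mm <- model.matrix(stats::delete.response(fit$terms), grid)
  colMeans(mm[, fit$coef_names, drop = FALSE])
}

#' @export
print.rm_lmm <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures LMM (REML), %s within-subject covariance\n",
    x$cov_type))
  cat(sprintf("  %d observations, %d subjects; -2 REML = %.3f%s\n",
              x$n_obs, x$n_subjects, x$neg2_reml,
              if (x$convergence != 0) " (NOT converged)" else ""))
  if (x$degenerate) cat("  [degenerate fit: constant response]\n")
  tab <- x$anova
  tab$F <- round(tab$F, 3)
  tab$df2 <- round(tab$df2, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up FDR adjustment of a keyed set of p-values (typically one per
#' ROI), with significance flags at level `q`.
#'
#' @param pvals named numeric vector of raw p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return data frame with columns `key`, `p`, `p_fdr`, `significant`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L)
    return(data.frame(key = character(0), p = numeric(0),
                      p_fdr = numeric(0), significant = logical(0)))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop_mvcsi("mvcsi_invalid", "p-values must lie in (0, 1]")
  keys <- if (is.null(names(pvals))) as.character(seq_along(pvals))
    else names(pvals)
  adj <- p.adjust(pvals, method = "BH")
  data.frame(key = keys, p = as.numeric(pvals), p_fdr = as.numeric(adj),
             significant = adj <= q, row.names = NULL)
}
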