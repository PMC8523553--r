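# Independent brute-force oracles used across tests.

# Pairwise Pearson + arctanh, one pair at a time.
brute_mvcs <- function(x) {
  n <- ncol(x)
  z <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    z[i, j] <- atanh(cor(x[, i], x[, j]))
  }
  z
}

# Direct enumeration of the scrubbing rule: each exceedance plus its
# successor is removed.
brute_censor_keep <- function(fd, thr = 0.5) {
  n <- length(fd)
  removed <- logical(n)
  for (t in seq_len(n)) {
    if (fd[t] > thr) {
      removed[t] <- TRUE
      if (t < n) removed[t + 1] <- TRUE
    }
  }
  which(!removed)
}

# Step-up Benjamini-Hochberg by hand: adjusted p and rejection flags.
brute_bh <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m / i * ranked[i])
    adj[i] <- prev
  }
  k <- which(ranked <= seq_len(m) / m * q)
  reject <- logical(m)
  if (length(k)) reject[seq_len(max(k))] <- TRUE
  out_adj <- numeric(m); out_rej <- logical(m)
  out_adj[o] <- adj; out_rej[o] <- reject
  list(adj = out_adj, reject = out_rej)
}

# Build a 3-voxel MVCS object with a prescribed strict upper triangle
# (column-major order: [1,2], [1,3], [2,3]).
mvcs_from_triangle <- function(ut, ids = paste0("v", 1:3)) {
  z <- matrix(0, 3, 3, dimnames = list(ids, ids))
  z[upper.tri(z)] <- ut
  z <- z + t(z)
  structure(list(z = z, n = 3, voxel_ids = ids, roi = NA, label = NA,
                 dropped_voxels = character(0)),
            class = "mvcs_matrix")
}

rand_run <- function(n_vol, n_vox, tr = 1) {
  roi_ts(matrix(rnorm(n_vol * n_vox), n_vol, n_vox), tr = tr)
}

# Long-format block-level behavioral dataset from the generator, with a
# stable per-subject baseline-speed offset (as in generate_experiment).
make_behavior_design <- function(n_subjects, seed, effects = list(),
                                 subject_sd_ms = 40) {
  set.seed(seed)
  des <- study_design(n_subjects)
  offs <- rnorm(n_subjects, 0, subject_sd_ms)
  names(offs) <- unique(des$subject)
  rows <- lapply(seq_len(nrow(des)), function(i) {
    args <- c(list(task = des$task[i],
                   baseline_rt_ms = 500 + offs[[des$subject[i]]]),
              effects)
    b <- do.call(generate_behavior, args)
    cbind(des[rep(i, length(unique(b$block))), ], block_performance(b))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
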