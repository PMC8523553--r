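#' Generate a synthetic key-press log
#'
#' One serial-reaction-time session: `n_blocks` practice blocks of
#' `presses_per_block` key presses on an 8-key board. In the SEQ task the
#' targets cycle a fixed 8-element sequence and block-mean reaction times
#' follow the exponential learning curve
#' `A + B * exp(-lambda * (block - 1))`; in the RND task targets are fresh
#' permutations of the 8 keys and block means stay flat at `A + B`.
#' Individual press RTs are log-normal around the block mean and
#' correctness is Bernoulli.
#'
#' @param task `"SEQ"` or `"RND"`.
#' @param n_blocks,presses_per_block schedule (defaults 16 x 48).
#' @param baseline_rt_ms asymptotic mean RT `A` (ms).
#' @param learning_amp_ms learning amplitude `B` (ms).
#' @param learning_rate exponential rate `lambda` per block.
#' @param accuracy probability that a press is correct.
#' @param rt_log_sd log-scale SD of press RTs.
#' @param sequence 8-element key sequence used in SEQ blocks.
#' @param seed optional seed.
#' @return data frame with columns `block`, `press`, `target_key`,
#'   `pressed_key`, `correct`, `rt_ms`.
#' @export
generate_behavior <- function(task = c("SEQ", "RND"), n_blocks = 16,
                              presses_per_block = 48,
                              baseline_rt_ms = 500, learning_amp_ms = 150,
                              learning_rate = 0.35, accuracy = 0.97,
                              rt_log_sd = 0.25,
                              sequence = c(4, 7, 3, 8, 6, 2, 5, 1),
                              seed = NULL) {
  task <- match.arg(task)
  if (n_blocks < 1 || presses_per_block < 1)
    stop_mvcsi("mvcsi_invalid", "counts must be >= 1")
  with_seed(seed, {
    n_press <- n_blocks * presses_per_block
    block <- rep(seq_len(n_blocks), each = presses_per_block)
    m_b <- if (task == "SEQ")
      baseline_rt_ms + learning_amp_ms * exp(-learning_rate * (block - 1))
    else rep(baseline_rt_ms + learning_amp_ms, n_press)
    # RT and correctness are drawn before the (task-dependent) target
    # stream, so SEQ and RND runs with the same seed share them exactly
    # when the learning amplitude is zero
    correct <- rbinom(n_press, 1, accuracy) == 1
    rt <- stats::rlnorm(n_press, meanlog = log(m_b) - rt_log_sd^2 / 2,
                        sdlog = rt_log_sd)
    n_oct <- ceiling(presses_per_block / 8)
    targets <- unlist(lapply(seq_len(n_blocks), function(b) {
      if (task == "SEQ") rep_len(sequence, presses_per_block)
      else unlist(lapply(seq_len(n_oct),
                         function(i) sample(8)))[seq_len(presses_per_block)]
    }))
    pressed <- targets
    wrong <- which(!correct)
    if (length(wrong))
      pressed[wrong] <- vapply(targets[wrong], function(k)
        sample(setdiff(1:8, k), 1), numeric(1))
    data.frame(block = block,
               press = rep(seq_len(presses_per_block), n_blocks),
               target_key = targets, pressed_key = pressed,
               correct = correct, rt_ms = rt)
  })
}

# Task-run volume schedule from a key-press log: practice block durations
# are the summed press RTs, with a fixed rest period after each block.
# Returns total volume count and annotations giving 1-based volume ranges
# per phase (a volume belongs to the phase covering its midpoint).
task_schedule <- function(keypresses, tr, rest_block_s = 15) {
  blocks <- sort(unique(keypresses$block))
  t0 <- 0
  events <- list()
  for (b in blocks) {
    dur <- sum(keypresses$rt_ms[keypresses$block == b]) / 1000
    events[[length(events) + 1L]] <- c(b, 0, t0, t0 + dur)  # practice
    t0 <- t0 + dur
    events[[length(events) + 1L]] <- c(b, 1, t0, t0 + rest_block_s)
    t0 <- t0 + rest_block_s
  }
  ev <- do.call(rbind, events)
  n_vol <- ceiling(t0 / tr)
  mid <- (seq_len(n_vol) - 0.5) * tr
  phase_of <- function(tm) {
    i <- which(ev[, 3] <= tm & tm < ev[, 4])[1]
    if (is.na(i)) c(NA, NA) else ev[i, 1:2]
  }
  ass <- t(vapply(mid, phase_of, numeric(2)))
  runs <- rle(paste(ass[, 1], ass[, 2]))
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  parts <- do.call(rbind, strsplit(runs$values, " "))
  # volumes past the final event (partial last TR) carry "NA" labels
  ann <- data.frame(block = strtoi(parts[, 1]),
                    phase = ifelse(parts[, 2] == "0", "practice", "rest"),
                    start_vol = starts, end_vol = ends)
  ann <- ann[!is.na(ann$block), , drop = FALSE]
  rownames(ann) <- NULL
  list(n_volumes = n_vol, annotations = ann)
}

#' Per-block SRTT performance measures
#'
#' Performance speed is the mean reaction time over correct presses only;
#' accuracy is the percentage of correct presses. Blocks without any
#' correct press get accuracy 0 and a missing (NA) mean RT.
#'
#' @param log a key-press data frame as produced by [generate_behavior()]
#'   (columns `block`, `correct`, `rt_ms`).
#' @return data frame with columns `block`, `mean_rt_correct`, `accuracy`.
#' @export
block_performance <- function(log) {
  need <- c("block", "correct", "rt_ms")
  if (!all(need %in% names(log)))
    stop_mvcsi("mvcsi_invalid", "key-press log must have columns %s",
               paste(need, collapse = ", "))
  if (any(log$rt_ms <= 0))
    stop_mvcsi("mvcsi_invalid", "reaction times must be positive")
  blocks <- sort(unique(log$block))
  out <- lapply(blocks, function(b) {
    rows <- log[log$block == b, ]
    ok <- rows$correct
    data.frame(block = b,
               mean_rt_correct = if (any(ok)) mean(rows$rt_ms[ok]) else
                 NA_real_,
               accuracy = 100 * mean(ok))
  })
  do.call(rbind, out)
}
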