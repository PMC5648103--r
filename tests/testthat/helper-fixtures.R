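# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

single_tube_template <- function() sleep_arena_template(n_tubes = 1,
                                                        margin_mm = 8)

# A short ground-truthed single-tube recording.
quick_recording <- function(duration_s = 60, fps = 3, seed = 1,
                            program = NULL, noise_sd = 5) {
  tpl <- single_tube_template()
  pr <- program %||% random_behavior_program(duration_s, seed = seed + 500)
  gen <- generate_arena_frames(tpl, list(`1` = pr), duration_s = duration_s,
                               fps = fps, noise_sd = noise_sd, seed = seed)
  gen
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Intensity-weighted centroid of the difference between two frames:
# the image-moment oracle used against rendered positions.
moment_centroid <- function(frame, reference) {
  d <- pmax(reference - frame, 0)
  tot <- sum(d)
  ys <- (seq_len(nrow(d)) - 1)
  xs <- (seq_len(ncol(d)) - 1)
  c(x = sum(d %*% xs) / tot,
    y = sum(ys %*% d) / tot)
}

# Independent closed-loop oracle: explicit discrete-event re-scan
# simulation built on the reference evaluator, no incremental state.
naive_closed_loop <- function(stream, pred, schedule = NULL, mask_s = 5,
                              tube_length_mm = NULL) {
  buffer <- stream[0, , drop = FALSE]
  mask_until <- -Inf
  events <- numeric(0)
  masked <- logical(nrow(stream))
  for (i in seq_len(nrow(stream))) {
    t <- stream$t[i]
    if (t <= mask_until + 1e-12) {
      masked[i] <- TRUE
      next
    }
    buffer <- rbind(buffer, stream[i, , drop = FALSE])
    if (evaluate_trigger(pred, buffer, t, tube_length_mm) &&
        (is.null(schedule) ||
           any(schedule[, 1] <= t & t < schedule[, 2]))) {
      events <- c(events, t)
      mask_until <- t + mask_s
      buffer <- stream[0, , drop = FALSE]   # clocks restart after the mask
    }
  }
  list(event_t = events, masked = masked)
}

# Exact two-sided rank-sum p-value by full enumeration of group
# assignments (no ties assumed), independent of stats::wilcox.test.
enumerate_ranksum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  rr <- rank(c(x, y))
  u_all <- colSums(matrix(rr[combs], nrow = m)) - m * (m + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# All predicate trees up to a given depth over a fixed leaf set.
enumerate_trees <- function(leaves, depth) {
  lv <- list(leaves)
  for (d in 2:depth) {
    prev <- do.call(c, lv)
    nxt <- list()
    for (p in prev) nxt[[length(nxt) + 1]] <- trg_not(p)
    for (a in prev) for (b in prev) {
      nxt[[length(nxt) + 1]] <- trg_and(a, b)
      nxt[[length(nxt) + 1]] <- trg_or(a, b)
    }
    lv <- list(prev, nxt)
  }
  do.call(c, lv)
}

# A structured 200-step state/position sequence exercising long immobility
# runs, midline oscillation and food-zone dwelling.
structured_stream <- function(n = 200, tube_length_mm = 60) {
  states <- rep(c(rep("immobile", 25), rep("walking", 10),
                  rep("micromovement", 8), rep("immobile", 5),
                  rep("walking", 2)), length.out = n)
  x <- rep(c(seq(2, 58, length.out = 25), seq(58, 2, length.out = 25)),
           length.out = n)
  x[seq(1, n, by = 17)] <- tube_length_mm / 2   # exact midline landings
  data.frame(t = (seq_len(n) - 1) * 0.8, state = states, x_mm = x)
}
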