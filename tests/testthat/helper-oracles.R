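# Independent brute-force oracles used across the tests. These deliberately
# recompute quantities by direct enumeration rather than reusing package code.

# Hampel identifier recomputed window by window with explicit index sets.
oracle_hampel <- function(x, window = 6, n_sigmas = 3, protect_first = 5) {
  n <- length(x)
  half <- window / 2
  out <- x
  flag <- logical(n)
  for (i in seq_len(n)) {
    if (i <= protect_first) next
    idx <- setdiff(intersect(seq(i - half, i + half), seq_len(n)), i)
    nb <- x[idx]
    med <- stats::median(nb)
    s <- 1.4826 * stats::median(abs(nb - med))
    hit <- if (s > 0) abs(x[i] - med) > n_sigmas * s else x[i] != med
    if (hit) {
      out[i] <- med
      flag[i] <- TRUE
    }
  }
  list(x = out, flag = flag)
}

# Benjamini-Hochberg step-up adjusted p-values by direct enumeration.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (k in rev(seq_len(m))) {
    val <- p[ord[k]] * m / k
    running_min <- min(running_min, val, 1)
    adj[ord[k]] <- running_min
  }
  adj
}

# Partial correlation via residual-on-residual regression.
oracle_partial_r <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# A single-block schedule for quick learner simulations.
one_block_schedule <- function(n_trials, block_type = "adaptation") {
  make_schedule(data.frame(block_label = "B1", period = "learning",
                           block_type = block_type, n_trials = n_trials))
}

# Noise-free learner parameters.
noise_free_params <- function(A, B, g = 0, savings_gain = 1) {
  learner_params(A = A, B = B, sigma_plan = 0, sigma_exec = 0, g = g,
                 savings_gain = savings_gain)
}

# Build a trajectory object from raw coordinates with defaults filled in.
path_traj <- function(t_ms, x_mm, y_mm, task = "reaching",
                      start_xy = c(0, 0), target_xy = c(-120, 0)) {
  vmr_trajectory(t_ms, x_mm, y_mm, start_xy, target_xy, task = task)
}

# Straight constant-speed path at a given angle relative to the target
# direction (deg CCW), default leftward target.
straight_path <- function(angle_deg = 0, length_mm = 120, duration_ms = 400,
                          task = "reaching", start_xy = c(0, 0),
                          target_xy = c(-120, 0)) {
  theta <- atan2(target_xy[2] - start_xy[2], target_xy[1] - start_xy[1]) +
    angle_deg * pi / 180
  t <- seq(0, duration_ms)
  r <- length_mm * t / duration_ms
  path_traj(t, start_xy[1] + r * cos(theta), start_xy[2] + r * sin(theta),
            task = task, start_xy = start_xy, target_xy = target_xy)
}

# Minimal cohort configuration for fast end-to-end runs.
small_cohort <- function(...) {
  cohort_config(n_per_condition = 2, ...)
}
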