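#' Tangential speed profile of a trajectory
#'
#' The path is smoothed with a centred moving average (window shrinking at
#' the ends) before centred finite differencing, to suppress sample-rate
#' quantisation noise without biasing the location of the speed peak.
#'
#' @param traj a [vmr_trajectory()].
#' @param smooth_window moving-average window, samples (odd; default 21).
#' @return numeric vector of speeds, mm/s, one per sample.
#' @export
trajectory_speed <- function(traj, smooth_window = 21) {
  sx <- moving_average(traj$x_mm, smooth_window)
  sy <- moving_average(traj$y_mm, smooth_window)
  n <- length(sx)
  t <- traj$t_ms
  i_prev <- c(1L, seq_len(n - 1L))
  i_next <- c(seq_len(n)[-1L], n)
  dt <- t[i_next] - t[i_prev]
  sqrt((sx[i_next] - sx[i_prev])^2 + (sy[i_next] - sy[i_prev])^2) / dt * 1000
}

# Signed angle (deg, CCW positive, wrapped) of start->point relative to
# start->target.
point_angle_deg <- function(p, start, target) {
  v <- p - start
  d <- target - start
  wrap_angle(rad2deg(atan2(v[2], v[1]) - atan2(d[2], d[1])))
}

#' Angular error at the point of peak cursor velocity
#'
#' The signed angle (degrees, counterclockwise positive) between the
#' start-to-target vector and the start-to-cursor vector at the sample of
#' maximum tangential speed. This is the reaching task's reference point:
#' it reflects the movement direction after any online correction up to the
#' speed peak.
#'
#' @inheritParams trajectory_speed
#' @return signed angular error in degrees, wrapped to (-180, 180].
#' @examples
#' tr <- simulate_trajectory(12, 30, task = "reaching")
#' angular_error_at_peak_velocity(tr)
#' @export
angular_error_at_peak_velocity <- function(traj, smooth_window = 21) {
  d <- sqrt((traj$x_mm - traj$start_xy[1])^2 + (traj$y_mm - traj$start_xy[2])^2)
  if (max(d) <= 0) stopf("no movement: trajectory never leaves the start")
  sp <- trajectory_speed(traj, smooth_window)
  idx <- which.max(sp)
  if (d[idx] <= 0) idx <- which(d > 0)[1]
  point_angle_deg(c(traj$x_mm[idx], traj$y_mm[idx]), traj$start_xy,
                  traj$target_xy)
}

#' Angular error at a fixed radius from the start
#'
#' The signed angle at the first point where the path's distance from the
#' start reaches `radius_mm`, interpolating linearly in x/y between the
#' bracketing samples. With the default 8 mm radius this is the curling
#' "release point", and serves as the matched early reference point when
#' comparing tasks.
#'
#' @inheritParams trajectory_speed
#' @param radius_mm reference radius, mm (default: the trajectory's release
#'   radius).
#' @return signed angular error in degrees, wrapped to (-180, 180].
#' @export
angular_error_at_radius <- function(traj, radius_mm = traj$release_radius_mm) {
  s <- traj$start_xy
  d <- sqrt((traj$x_mm - s[1])^2 + (traj$y_mm - s[2])^2)
  i1 <- which(d >= radius_mm)[1]
  if (is.na(i1)) stopf("radius not reached: path stays within %.3g mm", radius_mm)
  if (i1 == 1L) {
    p <- c(traj$x_mm[1], traj$y_mm[1])
  } else {
    p0 <- c(traj$x_mm[i1 - 1L], traj$y_mm[i1 - 1L])
    p1 <- c(traj$x_mm[i1], traj$y_mm[i1])
    # |p0 + lambda (p1 - p0) - s| = radius, lambda in [0, 1]
    v <- p1 - p0
    w <- p0 - s
    a <- sum(v^2)
    b <- 2 * sum(v * w)
    cc <- sum(w^2) - radius_mm^2
    disc <- max(b^2 - 4 * a * cc, 0)
    lambda <- (-b + sqrt(disc)) / (2 * a)
    lambda <- clamp(lambda, 0, 1)
    p <- p0 + lambda * v
  }
  point_angle_deg(p, s, traj$target_xy)
}

# time (ms) at which the path first crosses the given radius, linearly
# interpolated between the bracketing samples
radius_crossing_time <- function(traj, radius_mm) {
  s <- traj$start_xy
  d <- sqrt((traj$x_mm - s[1])^2 + (traj$y_mm - s[2])^2)
  i1 <- which(d >= radius_mm)[1]
  if (is.na(i1)) stopf("radius not reached: path stays within %.3g mm", radius_mm)
  if (i1 == 1L) return(traj$t_ms[1])
  frac <- (radius_mm - d[i1 - 1L]) / (d[i1] - d[i1 - 1L])
  traj$t_ms[i1 - 1L] + frac * (traj$t_ms[i1] - traj$t_ms[i1 - 1L])
}

#' Count substantial changes of movement direction
#'
#' Movement directions are computed from displacements between consecutive
#' non-stationary samples (zero-displacement samples are skipped, since
#' their direction is undefined); a direction change is counted whenever the
#' direction difference between two successive retained displacements
#' exceeds `threshold_deg`. Curved online corrections produce such changes;
#' a ballistic straight path produces none.
#'
#' @inheritParams trajectory_speed
#' @param threshold_deg direction-difference threshold, degrees (default 5).
#' @return non-negative integer count.
#' @export
count_direction_changes <- function(traj, threshold_deg = 5) {
  dx <- diff(traj$x_mm)
  dy <- diff(traj$y_mm)
  keep <- dx != 0 | dy != 0
  if (sum(keep) < 2L) stopf("too few moving samples to define directions")
  dirs <- rad2deg(atan2(dy[keep], dx[keep]))
  sum(abs(wrap_angle(diff(dirs))) > threshold_deg)
}

#' Duration of active cursor control
#'
#' Time from movement onset (first sample at which the smoothed tangential
#' speed exceeds `onset_frac` of its peak) to the end of active control: the
#' final sample for reaching (the cursor is steered until the target is
#' reached) and the release-radius crossing for curling (beyond it the
#' cursor is ballistic).
#'
#' @inheritParams trajectory_speed
#' @param onset_frac fraction of peak speed defining movement onset.
#' @return control time in ms.
#' @export
control_time <- function(traj, onset_frac = 0.05, smooth_window = 21) {
  sp <- trajectory_speed(traj, smooth_window)
  peak <- max(sp)
  if (peak <= 0) stopf("no movement: cannot detect onset")
  onset <- traj$t_ms[which(sp >= onset_frac * peak)[1]]
  end <- if (traj$task == "curling") {
    radius_crossing_time(traj, traj$release_radius_mm)
  } else {
    traj$t_ms[length(traj$t_ms)]
  }
  if (end <= onset) stopf("no active-control interval after onset")
  end - onset
}

#' Per-trial trajectory metrics table
#'
#' Applies the four trajectory measures to a list of trajectories and
#' returns a per-trial table (identifiers are taken from each trajectory's
#' `meta`).
#'
#' @param trajs list of [vmr_trajectory()] objects (e.g. from
#'   [simulate_trajectories()]).
#' @param radius_mm reference radius for the early matched reference point.
#' @return data.frame with columns `subject_id`, `task`, `block_label`,
#'   `trial_in_block`, `err_peakvel_deg`, `err_radius8_deg`,
#'   `n_dir_changes`, `control_time_ms`.
#' @export
trajectory_metrics <- function(trajs, radius_mm = 8) {
  rows <- lapply(trajs, function(tr) {
    m <- tr$meta
    data.frame(
      subject_id = m$subject_id %||% NA_character_,
      task = tr$task,
      block_label = m$block_label %||% NA_character_,
      trial_in_block = m$trial_in_block %||% NA_integer_,
      err_peakvel_deg = angular_error_at_peak_velocity(tr),
      err_radius8_deg = angular_error_at_radius(tr, radius_mm),
      n_dir_changes = count_direction_changes(tr),
      control_time_ms = control_time(tr),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
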