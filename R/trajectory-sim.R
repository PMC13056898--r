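#' Construct a cursor trajectory object
#'
#' A trajectory is one trial's sampled cursor path: time stamps (nominally
#' 1 kHz), x/y positions in mm, the start and target coordinates, the task
#' tag, and the release radius used as the curling reference point.
#'
#' @param t_ms strictly increasing sample times, ms.
#' @param x_mm,y_mm cursor positions, mm.
#' @param start_xy,target_xy length-2 coordinates, mm.
#' @param task `"reaching"` or `"curling"`.
#' @param release_radius_mm reference radius for the curling release point.
#' @param meta optional named list of identifiers (subject, block, trial).
#' @return an object of class `vmr_trajectory`.
#' @export
vmr_trajectory <- function(t_ms, x_mm, y_mm, start_xy, target_xy,
                           task = c("reaching", "curling"),
                           release_radius_mm = 8, meta = list()) {
  task <- match.arg(task)
  n <- length(t_ms)
  if (n < 2L) stopf("a trajectory needs at least 2 samples")
  if (length(x_mm) != n || length(y_mm) != n) {
    stopf("t_ms, x_mm, y_mm must have equal length")
  }
  if (any(diff(t_ms) <= 0)) stopf("t_ms must be strictly increasing")
  if (length(start_xy) != 2L || length(target_xy) != 2L) {
    stopf("start_xy and target_xy must be length-2 coordinates")
  }
  if (isTRUE(all(start_xy == target_xy))) stopf("target coincides with start")
  structure(list(t_ms = as.numeric(t_ms), x_mm = as.numeric(x_mm),
                 y_mm = as.numeric(y_mm),
                 start_xy = as.numeric(start_xy),
                 target_xy = as.numeric(target_xy),
                 task = task, release_radius_mm = release_radius_mm,
                 meta = meta),
            class = "vmr_trajectory")
}

#' @export
print.vmr_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %d samples over %.0f ms\n", x$task,
              length(x$t_ms), diff(range(x$t_ms))))
  invisible(x)
}

#' Default workspace geometry
#'
#' Start at the origin with a single leftward target 120 mm away (the 12 cm
#' start-to-target extent of the task workspace).
#' @return list with `start_xy` and `target_xy` (mm).
#' @export
default_geometry <- function() {
  list(start_xy = c(0, 0), target_xy = c(-120, 0))
}

#' Synthesise cursor trajectories consistent with a trial table
#'
#' Builds an idealised sampled path (1 kHz) for each trial row such that the
#' trajectory metrics recover the table's angular errors:
#'
#' * Curling: a straight path along the measured error direction. The launch
#'   phase accelerates linearly to 160 mm/s over 100 ms, crossing the release
#'   radius (8 mm) at its end; the autonomous phase continues straight at
#'   210 mm/s until the cursor reaches the target's horizontal coordinate.
#'   The angular error at the release radius equals the table's error.
#' * Reaching: the radial distance from the start follows a minimum-jerk
#'   profile over 600 ms, so tangential speed peaks mid-movement (300 ms).
#'   The position angle holds the planned error until the online-correction
#'   onset (150 ms, after the release-radius crossing), blends smoothly to
#'   the measured error before the speed peak, holds it across the peak, and
#'   then drifts partway toward the target. The angular error at the 8 mm
#'   radius therefore equals the planned error and the angular error at peak
#'   velocity equals the measured error.
#'
#' @param table a trial table (see [simulate_learner()]). If a
#'   `planned_error_deg` column is present it provides the pre-correction
#'   error for reaching trials; otherwise the measured error is used.
#' @param geometry list with `start_xy` and `target_xy`, see
#'   [default_geometry()].
#' @param release_radius_mm release radius, mm.
#' @param seed optional seed (paths are currently deterministic given the
#'   table; the argument is accepted for interface stability).
#' @return a list of [vmr_trajectory()] objects, one per table row, named
#'   `subject/task/block/trial`.
#' @examples
#' sched <- make_schedule(data.frame(block_label = "BL", period = "learning",
#'                                   block_type = "baseline", n_trials = 3))
#' p <- learner_params(sigma_plan = 0, sigma_exec = 0)
#' tab <- simulate_learner(p, sched, "curling", seed = 1)
#' trajs <- simulate_trajectories(tab)
#' angular_error_at_radius(trajs[[1]], 8)
#' @export
simulate_trajectories <- function(table, geometry = default_geometry(),
                                  release_radius_mm = 8, seed = NULL) {
  if (!is.data.frame(table) || !nrow(table)) stopf("table must be a non-empty data.frame")
  if (!"angular_error_deg" %in% names(table)) {
    stopf("table must have an angular_error_deg column")
  }
  if (!is.null(seed)) set.seed(seed)
  if (sqrt(sum((geometry$target_xy - geometry$start_xy)^2)) <= 0) {
    stopf("degenerate geometry: target coincides with start")
  }
  planned <- if ("planned_error_deg" %in% names(table)) {
    table$planned_error_deg
  } else {
    table$angular_error_deg
  }
  out <- vector("list", nrow(table))
  nm <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    task <- as.character(table$task[i])
    out[[i]] <- simulate_trajectory(
      angular_error_deg = table$angular_error_deg[i],
      planned_error_deg = planned[i],
      task = task, geometry = geometry,
      release_radius_mm = release_radius_mm,
      meta = list(subject_id = as.character(table$subject_id[i] %||% "S01"),
                  task = task,
                  block_label = as.character(table$block_label[i] %||% "B1"),
                  trial_in_block = table$trial_in_block[i] %||% i)
    )
    m <- out[[i]]$meta
    nm[i] <- paste(m$subject_id, m$task, m$block_label, m$trial_in_block,
                   sep = "/")
  }
  names(out) <- nm
  out
}

#' Synthesise a single trial's trajectory
#'
#' @inheritParams simulate_trajectories
#' @param angular_error_deg the measured angular error at the task's
#'   reference point (peak velocity for reaching, release radius for curling).
#' @param planned_error_deg the pre-correction error (reaching only; the
#'   error expressed at the release radius). Defaults to the measured error.
#' @param task `"reaching"` or `"curling"`.
#' @param meta optional identifier list attached to the trajectory.
#' @return a [vmr_trajectory()] object.
#' @export
simulate_trajectory <- function(angular_error_deg,
                                planned_error_deg = angular_error_deg,
                                task = c("reaching", "curling"),
                                geometry = default_geometry(),
                                release_radius_mm = 8, meta = list()) {
  task <- match.arg(task)
  start <- geometry$start_xy
  target <- geometry$target_xy
  dvec <- target - start
  dist <- sqrt(sum(dvec^2))
  if (dist <= 0) stopf("degenerate geometry: target coincides with start")
  theta_target <- atan2(dvec[2], dvec[1])

  if (task == "curling") {
    path <- curling_path(deg2rad(angular_error_deg), theta_target, start,
                         target, release_radius_mm)
  } else {
    path <- reaching_path(deg2rad(angular_error_deg),
                          deg2rad(planned_error_deg), theta_target, start,
                          dist)
  }
  vmr_trajectory(path$t, path$x, path$y, start, target, task,
                 release_radius_mm, meta)
}

# Straight path: linear speed ramp to 160 mm/s over the 100 ms launch phase
# (8 mm travelled), then 210 mm/s until the target's horizontal coordinate
# (along the start->target axis) is reached; capped at 2.5 x target distance
# for near-perpendicular errors.
curling_path <- function(err_rad, theta_target, start, target, release_radius) {
  theta <- theta_target + err_rad
  u <- c(cos(theta), sin(theta))
  launch_ms <- 100
  v_release <- 2 * release_radius / (launch_ms / 1000)  # mm/s
  v_auto <- 210

  dist <- sqrt(sum((target - start)^2))
  # distance along u until the projection on the target axis is covered
  axis <- (target - start) / dist
  proj <- sum(u * axis)
  r_stop <- if (proj > 0.05) dist / proj else Inf
  r_stop <- min(max(r_stop, release_radius * 1.5), 2.5 * dist)
  t_end <- launch_ms + (r_stop - release_radius) / v_auto * 1000

  t <- seq(0, ceiling(t_end))
  ts <- t / 1000
  r_of_t <- ifelse(t <= launch_ms,
                   v_release * ts^2 / (2 * (launch_ms / 1000)),
                   release_radius + v_auto * (ts - launch_ms / 1000))
  r_of_t <- pmin(r_of_t, r_stop)
  list(t = t, x = start[1] + r_of_t * u[1], y = start[2] + r_of_t * u[2])
}

# Polar construction about the start: minimum-jerk radial profile (speed
# peak at half-time) with the position angle piecewise constant/blended so
# the radius-8 and peak-velocity reference points carry the planned and
# measured error exactly.
reaching_path <- function(err_rad, plan_rad, theta_target, start, dist) {
  T_ms <- 600
  t <- seq(0, T_ms)
  tau <- t / T_ms
  r_of_t <- dist * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)

  th_p <- theta_target + plan_rad
  th_m <- theta_target + err_rad
  t_on <- 150    # online-correction onset (visuomotor latency)
  t_blend_end <- 240
  t_hold_end <- 360  # speed peak at 300 ms falls inside the hold window
  th_end <- theta_target + err_rad / 3

  phi <- numeric(length(t))
  seg1 <- t <= t_on
  seg2 <- t > t_on & t <= t_blend_end
  seg3 <- t > t_blend_end & t <= t_hold_end
  seg4 <- t > t_hold_end
  phi[seg1] <- th_p
  s2 <- (t[seg2] - t_on) / (t_blend_end - t_on)
  phi[seg2] <- th_p + (th_m - th_p) * (1 - cos(pi * s2)) / 2
  phi[seg3] <- th_m
  s4 <- (t[seg4] - t_hold_end) / (T_ms - t_hold_end)
  phi[seg4] <- th_m + (th_end - th_m) * (1 - cos(pi * s4)) / 2

  list(t = t, x = start[1] + r_of_t * cos(phi), y = start[2] + r_of_t * sin(phi))
}
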