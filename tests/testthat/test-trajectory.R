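test_that("straight paths give constant angular error at every reference", {
  tr0 <- straight_path(0)
  expect_equal(angular_error_at_peak_velocity(tr0), 0, tolerance = 1e-8)
  expect_equal(angular_error_at_radius(tr0, 8), 0, tolerance = 1e-8)

  tr10 <- straight_path(10)
  expect_equal(angular_error_at_peak_velocity(tr10), 10, tolerance = 1e-6)
  expect_equal(angular_error_at_radius(tr10, 8), 10, tolerance = 1e-6)
  expect_equal(angular_error_at_radius(tr10, 50), 10, tolerance = 1e-6)
})

test_that("a path crossing the radius on the target line scores zero", {
  # pass exactly through (r cos 180, r sin 180) for the leftward target
  r <- 8
  t <- seq(0, 200)
  x <- -t * 0.1
  y <- rep(0, length(t))
  tr <- path_traj(t, x, y)
  expect_equal(angular_error_at_radius(tr, r), 0, tolerance = 1e-8)
})

test_that("peak-velocity error on a curved path matches a raw-sample oracle", {
  # first 100 ms straight at +30 deg, then curving onto the target line,
  # with speed peaking in the second segment
  t <- seq(0, 500)
  th0 <- pi + 30 * pi / 180
  r1 <- 0.05 * (0:100)                      # slow straight segment, 5 mm
  ang <- th0 + (pi - th0) * seq(0, 1, length.out = 401)[-1]
  # faster second segment: radial growth accelerating then decelerating
  s <- seq(0, 1, length.out = 401)[-1]
  r2 <- 5 + 90 * (3 * s^2 - 2 * s^3)
  x <- c(r1 * cos(th0), r2 * cos(ang))
  y <- c(r1 * sin(th0), r2 * sin(ang))
  tr <- path_traj(t, x, y)
  got <- angular_error_at_peak_velocity(tr)
  expect_gt(got, 0)
  expect_lt(got, 30)
  # brute force on the raw samples, no smoothing
  vx <- diff(x) / diff(t)
  vy <- diff(y) / diff(t)
  sp <- sqrt(vx^2 + vy^2)
  i <- which.max(sp)
  brute <- (atan2(y[i], x[i]) - pi) * 180 / pi
  brute <- ((brute + 180) %% 360) - 180
  expect_equal(got, brute, tolerance = 0.5)
})

test_that("direction changes count only super-threshold turns", {
  expect_equal(count_direction_changes(straight_path(5)), 0)

  turn_path <- function(turn_deg) {
    t <- seq(0, 200)
    th1 <- pi
    th2 <- pi + turn_deg * pi / 180
    x1 <- cumsum(rep(cos(th1) * 0.5, 100))
    y1 <- cumsum(rep(sin(th1) * 0.5, 100))
    x <- c(0, x1, x1[100] + cumsum(rep(cos(th2) * 0.5, 100)))
    y <- c(0, y1, y1[100] + cumsum(rep(sin(th2) * 0.5, 100)))
    path_traj(t, x, y)
  }
  expect_equal(count_direction_changes(turn_path(10)), 1)
  expect_equal(count_direction_changes(turn_path(4)), 0)

  # stationary samples are skipped, not counted as turns
  t <- seq(0, 10)
  x <- c(0, -1, -1, -1, -2, -3, -4, -5, -6, -7, -8)
  y <- rep(0, 11)
  expect_equal(count_direction_changes(path_traj(t, x, y)), 0)
})

test_that("control time follows task-specific endpoints", {
  # constant 80 mm/s curling path: 8 mm release radius at 100 ms
  t <- seq(0, 300)
  x <- -0.08 * t
  y <- rep(0, length(t))
  ct <- control_time(path_traj(t, x, y, task = "curling"))
  expect_equal(ct, 100, tolerance = 2)

  # reaching: onset to trial end
  tr <- straight_path(0, duration_ms = 500)
  ct2 <- control_time(tr)
  expect_gt(ct2, 450)  # constant speed: onset at the first sample
  expect_lte(ct2, 500)

  # curling path that never reaches the release radius errors out
  short <- path_traj(seq(0, 100), -0.05 * seq(0, 100), rep(0, 101),
                     task = "curling")
  expect_error(control_time(short), "radius not reached")
})

test_that("metrics are equivariant under rotation and invariant to scale", {
  set.seed(42)
  for (rep in 1:20) {
    err <- runif(1, -30, 30)
    plan <- err + runif(1, -10, 10)
    task <- sample(c("reaching", "curling"), 1)
    tr <- simulate_trajectory(err, plan, task = task)
    base_pv <- angular_error_at_peak_velocity(tr)
    base_r8 <- angular_error_at_radius(tr, 8)
    base_dc <- count_direction_changes(tr)

    theta <- runif(1, -pi, pi)
    Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    # joint rotation of path and target: all metrics unchanged
    pj <- Rm %*% rbind(tr$x_mm, tr$y_mm)
    tgt <- as.numeric(Rm %*% tr$target_xy)
    trj <- vmr_trajectory(tr$t_ms, pj[1, ], pj[2, ], c(0, 0), tgt, tr$task)
    expect_equal(angular_error_at_peak_velocity(trj), base_pv,
                 tolerance = 1e-6)
    expect_equal(angular_error_at_radius(trj, 8), base_r8, tolerance = 1e-6)
    expect_equal(count_direction_changes(trj), base_dc)

    # path-only rotation adds theta to the angular errors
    trp <- vmr_trajectory(tr$t_ms, pj[1, ], pj[2, ], c(0, 0), tr$target_xy,
                          tr$task)
    th_deg <- theta * 180 / pi
    expect_equal(wrap_angle(angular_error_at_radius(trp, 8) - th_deg),
                 base_r8, tolerance = 1e-6)

    # uniform spatial scaling leaves angles and counts unchanged
    trs <- vmr_trajectory(tr$t_ms, 2.5 * tr$x_mm, 2.5 * tr$y_mm, c(0, 0),
                          2.5 * tr$target_xy, tr$task,
                          release_radius_mm = 2.5 * tr$release_radius_mm)
    expect_equal(angular_error_at_radius(trs, 2.5 * 8), base_r8,
                 tolerance = 1e-6)
    expect_equal(count_direction_changes(trs), base_dc)
  }
})

test_that("interpolated radius crossing brackets the first-crossing sample", {
  set.seed(7)
  for (rep in 1:20) {
    tr <- simulate_trajectory(runif(1, -30, 30), task = "curling")
    d <- sqrt((tr$x_mm - tr$start_xy[1])^2 + (tr$y_mm - tr$start_xy[2])^2)
    i_brute <- which(d >= 8)[1]
    t_cross <- vmadapt:::radius_crossing_time(tr, 8)
    expect_gte(t_cross, tr$t_ms[i_brute - 1])
    expect_lte(t_cross, tr$t_ms[i_brute])
  }
})

test_that("synthetic trajectories round-trip the trial table errors", {
  sched <- one_block_schedule(8)
  p <- learner_params(A = 0.95, B = 0.25, sigma_plan = 3, sigma_exec = 2,
                      g = 0.5)
  reach <- simulate_learner(p, sched, "reaching", seed = 31)
  curl <- simulate_learner(learner_params(A = 0.95, B = 0.25, sigma_plan = 3,
                                          sigma_exec = 2), sched, "curling",
                           seed = 32)
  tm_r <- trajectory_metrics(simulate_trajectories(reach))
  tm_c <- trajectory_metrics(simulate_trajectories(curl))
  # reaching: peak-velocity error = measured, release-radius error = planned
  expect_equal(tm_r$err_peakvel_deg, reach$angular_error_deg,
               tolerance = 0.2)
  expect_equal(tm_r$err_radius8_deg, reach$planned_error_deg,
               tolerance = 0.2)
  # curling: error identical at both references (straight path), 0.1 deg
  expect_equal(tm_c$err_radius8_deg, curl$angular_error_deg,
               tolerance = 0.1)
  expect_equal(tm_c$err_peakvel_deg, curl$angular_error_deg,
               tolerance = 0.1)
  # reaching shows larger errors at the matched early radius than curling
  expect_gt(mean(abs(tm_r$err_radius8_deg)), mean(abs(tm_r$err_peakvel_deg)))
})

test_that("degenerate trajectories are rejected", {
  expect_error(vmr_trajectory(0:10, rep(0, 11), rep(0, 11), c(0, 0), c(0, 0)),
               "target coincides")
  expect_error(angular_error_at_peak_velocity(
    path_traj(0:10, rep(0, 11), rep(0, 11))), "no movement")
  expect_error(angular_error_at_radius(straight_path(0, length_mm = 5), 8),
               "radius not reached")
  expect_error(count_direction_changes(path_traj(0:2, c(0, 0, 0), c(0, 0, 0))),
               "too few")
})
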