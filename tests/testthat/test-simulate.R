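test_that("noise-free learner follows the state-space recurrence exactly", {
  sched <- one_block_schedule(6)
  # A = 1, B = 1: the whole error is learned after one trial
  t1 <- simulate_learner(noise_free_params(1, 1), sched, "curling")
  expect_equal(t1$angular_error_deg, c(40, 0, 0, 0, 0, 0))
  # A = 1, B = 0.5: geometric halving
  t2 <- simulate_learner(noise_free_params(1, 0.5), sched, "curling")
  expect_equal(t2$angular_error_deg, c(40, 20, 10, 5, 2.5, 1.25))
})

test_that("online correction scales measured errors but not the state", {
  sched <- one_block_schedule(10)
  curl <- simulate_learner(noise_free_params(1, 0.5), sched, "curling")
  reach <- simulate_learner(noise_free_params(1, 0.5, g = 0.5), sched,
                            "reaching")
  expect_equal(reach$angular_error_deg, 0.5 * curl$angular_error_deg)
  # the between-trial update consumes the pre-correction error, so the
  # planned series is identical across tasks
  expect_equal(reach$planned_error_deg, curl$planned_error_deg)
})

test_that("noise-free errors converge to the closed-form fixed point", {
  sched <- one_block_schedule(500)
  for (A in c(0.9, 0.95)) {
    for (B in c(0.1, 0.3)) {
      tab <- simulate_learner(noise_free_params(A, B), sched, "curling")
      expect_equal(tail(tab$angular_error_deg, 1),
                   40 * (1 - A) / (1 - A + B), tolerance = 1e-6)
    }
  }
  tabA1 <- simulate_learner(noise_free_params(1, 0.2), sched, "curling")
  expect_lt(abs(tail(tabA1$angular_error_deg, 1)), 1e-6)
})

test_that("savings gain accelerates relearning block over block", {
  sched <- make_schedule()
  p <- learner_params(A = 0.95, B = 0.2, sigma_plan = 0, sigma_exec = 0,
                      savings_gain = 1.2)
  tab <- simulate_learner(p, sched, "curling")
  early <- sapply(paste0("Ad", 1:5), function(b) {
    mean(tab$angular_error_deg[tab$block_label == b & tab$trial_in_block <= 5])
  })
  expect_true(all(diff(early) < 0))
  # without savings and with exact state reset, adaptation blocks repeat
  p0 <- noise_free_params(0.95, 0.2)
  tab0 <- simulate_learner(p0, sched, "curling")
  series <- lapply(paste0("Ad", 1:5), function(b) {
    tab0$angular_error_deg[tab0$block_label == b]
  })
  for (k in 2:5) expect_equal(series[[k]], series[[1]])
})

test_that("de-adaptation and washout blocks show rebound aftereffects", {
  sched <- make_schedule()
  tab <- simulate_learner(noise_free_params(0.95, 0.3), sched, "curling")
  # first washout trial reflects the state carried out of the preceding
  # adaptation block: a negative (opposite-direction) error
  w1 <- tab$angular_error_deg[tab$block_label == "Wash" &
                                tab$trial_in_block == 1]
  expect_lt(w1, -5)
  bl <- tab$angular_error_deg[tab$block_type == "baseline"]
  expect_true(all(bl == 0))
})

test_that("cohort simulation is seed-deterministic and balanced", {
  cfg <- small_cohort()
  a <- simulate_cohort(cfg, make_schedule(), seed = 11)
  b <- simulate_cohort(cfg, make_schedule(), seed = 11)
  expect_identical(a, b)
  c2 <- simulate_cohort(cfg, make_schedule(), seed = 12)
  expect_false(identical(a$angular_error_deg, c2$angular_error_deg))
  counts <- table(a$condition, a$task) / 560
  expect_true(all(counts == cfg$n_per_condition))
})

test_that("degenerate noise-free cohort collapses to identical series", {
  cfg <- cohort_config(n_per_condition = 2, A_sd = 0, B_sd = 0,
                       sigma_plan_mean = 0, sigma_plan_sd = 0,
                       sigma_exec_mean = 0, sigma_exec_sd = 0,
                       g_sd = 0, delta_g_reinforced = 0,
                       savings_gain_sd = 0, rho_plan_B = 0)
  tab <- simulate_cohort(cfg, make_schedule(), seed = 5)
  sp <- attr(tab, "subject_params")
  expect_true(all(sp$g_reaching == sp$g_reaching[1]))
  expect_true(all(sp$B_curling == sp$B_curling[1]))
  # every same-task subject produces the identical error series
  for (task in c("reaching", "curling")) {
    series <- split(tab$angular_error_deg[tab$task == task],
                    tab$subject_id[tab$task == task])
    for (k in seq_along(series)) expect_equal(series[[k]], series[[1]])
  }
})

test_that("measured-error variability increases with both noise sources", {
  sched <- one_block_schedule(5)
  # a shallow learning trend (small B) keeps the 5-trial SD noise-dominated
  early_sd <- function(sp, se, block) {
    sds <- sapply(1:30, function(s) {
      p <- learner_params(A = 0.95, B = 0.05, sigma_plan = sp, sigma_exec = se)
      sd(simulate_learner(p, sched, "curling",
                          seed = 10000 * block + s)$angular_error_deg)
    })
    mean(sds)
  }
  grid_plan <- mapply(early_sd, sp = c(0, 2, 5, 9), block = 1:4, se = 1)
  grid_exec <- mapply(function(se, block) early_sd(0.5, se, block),
                      se = c(0, 2, 5, 9), block = 5:8)
  expect_equal(order(grid_plan), 1:4)
  expect_equal(order(grid_exec), 1:4)
})

test_that("payoff rule awards 0-10 points during learning only", {
  sched <- make_schedule()
  p <- noise_free_params(1, 1)  # error 40 on trial 1, then 0: near-perfect
  rew <- simulate_learner(p, sched, "reaching", condition = "reward")
  pun <- simulate_learner(p, sched, "reaching", condition = "punishment")
  neu <- simulate_learner(p, sched, "reaching", condition = "neutral")
  expect_true(all(is.na(neu$points_awarded)))
  learn <- rew$period == "learning"
  expect_true(all(is.na(rew$points_awarded[!learn])))
  expect_true(all(rew$points_awarded[learn] %in% 0:10))
  expect_true(all(pun$points_awarded[learn] %in% -(10:0)))
  # perfect trials score the maximum: 10 gained / 0 lost
  perfect <- learn & rew$angular_error_deg == 0
  expect_true(all(rew$points_awarded[perfect] == 10))
  expect_true(all(pun$points_awarded[perfect] == 0))
  # punishment running total starts from the endowment
  expect_equal(PUNISHMENT_ENDOWMENT + sum(pun$points_awarded[learn]),
               4000 + sum(pun$points_awarded[learn]))
  expect_lte(PUNISHMENT_ENDOWMENT + sum(pun$points_awarded[learn]), 4000)
})

test_that("reinforcement manipulates reaching only, by construction", {
  cfg <- cohort_config(n_per_condition = 3, A_sd = 0, B_sd = 0,
                       sigma_plan_sd = 0, sigma_exec_sd = 0, g_sd = 0,
                       savings_gain_sd = 0, rho_plan_B = 0)
  tab <- simulate_cohort(cfg, make_schedule(), seed = 2)
  sp <- attr(tab, "subject_params")
  g_by_cond <- tapply(sp$g_reaching, sp$condition, unique)
  expect_equal(unname(g_by_cond[["reward"]] - g_by_cond[["neutral"]]),
               cfg$delta_g_reinforced)
  expect_equal(unname(g_by_cond[["punishment"]]), unname(g_by_cond[["reward"]]))
  # curling parameters do not depend on condition
  expect_equal(length(unique(sp$B_curling)), 1L)
})
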