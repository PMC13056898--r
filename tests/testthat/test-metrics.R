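make_block_table <- function(errors, subject_id = "S1", task = "curling",
                             block_label = "Ad1", block_type = "adaptation",
                             period = "learning", removed = NULL) {
  n <- length(errors)
  tab <- data.frame(
    subject_id = subject_id, task = task, condition = "neutral",
    period = period, block_label = block_label, block_type = block_type,
    trial_in_block = seq_len(n), rotation_deg = 40,
    angular_error_deg = errors, points_awarded = NA_integer_,
    is_outlier_removed = FALSE, is_hampel_replaced = FALSE,
    stringsAsFactors = FALSE
  )
  if (!is.null(removed)) tab$is_outlier_removed[removed] <- TRUE
  tab
}

test_that("block summaries compute windowed means by original trial index", {
  const <- block_summaries(make_block_table(rep(7, 40)))
  expect_equal(const$mean_error, 7)
  expect_equal(const$early_mean, 7)
  expect_equal(const$late_mean, 7)
  expect_equal(const$early_sd, 0)
  expect_equal(const$early_improvement, 0)
  expect_false(const$partial)

  dec <- block_summaries(make_block_table(c(40, 30, 20, 10, 5, rep(2, 35))))
  expect_equal(dec$early_improvement, 35)
  expect_equal(dec$early_mean, mean(c(40, 30, 20, 10, 5)))
  expect_equal(dec$late_mean, 2)

  # removed interior trial: early mean over the surviving 4, flagged partial
  part <- block_summaries(make_block_table(c(40, 30, 20, 10, 5, rep(2, 35)),
                                           removed = 3))
  expect_equal(part$early_mean, mean(c(40, 30, 10, 5)))
  expect_true(part$partial)
  expect_equal(part$n_used, 39)
})

test_that("savings curve decreases with the savings gain and is flat without", {
  sched <- make_schedule()
  p <- noise_free_params(0.95, 0.2)
  tab0 <- simulate_learner(p, sched, "curling")
  m0 <- block_summaries(tab0)
  s0 <- savings_curve(m0)
  expect_equal(length(unique(round(s0$curve$early_mean, 10))), 1)

  # two-block arithmetic example
  two <- rbind(make_block_table(rep(20, 40), block_label = "Ad1"),
               make_block_table(rep(12, 40), block_label = "Ad2"))
  s2 <- savings_curve(block_summaries(two))
  expect_equal(s2$diffs$mean_diff, 8)

  # Monte-Carlo: with savings_gain > 1 early means decrease in expectation
  early <- matrix(0, 6, 5)
  for (s in 1:6) {
    p1 <- learner_params(A = 0.95, B = 0.2, sigma_plan = 2, sigma_exec = 1,
                         savings_gain = 1.2)
    t1 <- simulate_learner(p1, sched, "curling", seed = s)
    m1 <- block_summaries(t1)
    ad <- m1[m1$block_type == "adaptation" & m1$period == "learning", ]
    early[s, ] <- ad$early_mean[match(paste0("Ad", 1:5), ad$block_label)]
  }
  expect_true(all(diff(colMeans(early)) < 0))
  expect_error(savings_curve(block_summaries(make_block_table(rep(1, 40)))),
               "at least 2")
})

test_that("retention contrast reproduces the paired-t formula", {
  mk <- function(vals, label, period) {
    do.call(rbind, lapply(seq_along(vals), function(i) {
      make_block_table(rep(vals[i], 40), subject_id = paste0("S", i),
                       block_label = label, period = period)
    }))
  }
  last <- c(10, 12, 9, 14, 11)
  first <- c(8, 9, 8, 10, 9)
  tab <- rbind(mk(last, "Ad5", "learning"), mk(first, "Ret1", "retention"))
  res <- retention_contrast(block_summaries(tab))
  d <- last - first
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_hand)
  expect_equal(res$mean_diff, mean(d))
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4))

  same <- rbind(mk(last, "Ad5", "learning"), mk(last, "Ret1", "retention"))
  res0 <- retention_contrast(block_summaries(same))
  expect_equal(res0$mean_diff, 0)
  expect_equal(res0$t, 0)

  missing <- tab[!(tab$subject_id == "S5" & tab$block_label == "Ret1"), ]
  expect_error(retention_contrast(block_summaries(missing)), "missing")
})

test_that("washout change is the baseline-to-washout shift in error magnitude", {
  mk2 <- function(bl, wa, sid) {
    rbind(make_block_table(rep(bl, 40), subject_id = sid, block_label = "BL",
                           block_type = "baseline"),
          make_block_table(rep(wa, 40), subject_id = sid, block_label = "Wash",
                           block_type = "washout", period = "retention"))
  }
  tab <- rbind(mk2(2, 3, "S1"), mk2(1, 1, "S2"))
  res <- washout_change(tab)
  expect_equal(res$by_subject$change[res$by_subject$subject_id == "S1"], 1)
  expect_equal(res$by_subject$change[res$by_subject$subject_id == "S2"], 0)

  # simulator default: positive aftereffect in both tasks
  sched <- make_schedule()
  changes <- sapply(1:5, function(s) {
    p <- learner_params(A = 0.95, B = 0.2, sigma_plan = 2, sigma_exec = 1)
    tabs <- simulate_learner(p, sched, "curling", seed = s)
    mean(washout_change(tabs)$by_subject$change)
  })
  expect_true(all(changes > 0))
})

test_that("condition contrasts match hand-computed one-way ANOVA", {
  d <- data.frame(condition = rep(c("a", "b", "c"), each = 3),
                  mean_error = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  res <- condition_contrasts(d)
  grand <- mean(d$mean_error)
  ssb <- 3 * sum((tapply(d$mean_error, d$condition, mean) - grand)^2)
  ssw <- sum((d$mean_error - rep(tapply(d$mean_error, d$condition, mean),
                                 each = 3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$anova$F, f_hand)
  expect_equal(res$anova$df1, 2)
  expect_equal(res$anova$df2, 6)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p))

  flat <- data.frame(condition = rep(c("a", "b"), each = 3), mean_error = 5)
  expect_equal(condition_contrasts(flat)$anova$F, 0)

  small <- data.frame(condition = c("a", "a", "b"), mean_error = c(1, 2, 3))
  expect_error(condition_contrasts(small), "fewer than 2")
})

test_that("BH adjustment matches the step-up enumeration oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
  set.seed(11)
  grid <- c(0.001, 0.01, 0.02, 0.04, 0.05, 0.2, 0.5, 0.9)
  for (rep in 1:50) {
    m <- sample(2:8, 1)
    p <- sample(grid, m, replace = TRUE)
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # monotonicity: adjusted values non-decreasing in sorted raw p
  p <- sort(runif(8))
  adj <- p.adjust(p, method = "BH")
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
})

test_that("partial correlation agrees with the residual-regression oracle", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(6:40, 1)
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    got <- partial_correlation(x, y, z)
    expect_equal(got$estimate, oracle_partial_r(x, y, z), tolerance = 1e-12)
  }

  # y = x exactly: partial correlation is 1
  x <- rnorm(10)
  z <- rnorm(10)
  expect_equal(partial_correlation(x, x, z)$estimate, 1, tolerance = 1e-12)

  # control variable with zero sample correlation to both: partial = plain r
  set.seed(5)
  x <- rnorm(20)
  y <- x + rnorm(20)
  z0 <- rnorm(20)
  z <- residuals(lm(z0 ~ x + y))  # orthogonal to both by construction
  got <- partial_correlation(x, y, z)
  expect_equal(got$estimate, cor(x, y), tolerance = 1e-12)

  # hand-built 6-point dataset
  x6 <- c(1, 2, 3, 4, 5, 6)
  y6 <- c(2, 1, 4, 3, 6, 5)
  z6 <- c(1, 1, 2, 2, 3, 4)
  expect_equal(partial_correlation(x6, y6, z6)$estimate,
               oracle_partial_r(x6, y6, z6), tolerance = 1e-12)

  expect_error(partial_correlation(c(1, 1, 1, 1), rnorm(4), rnorm(4)),
               "zero variance")
  expect_error(partial_correlation(rnorm(3), rnorm(3), rnorm(3)), "at least 4")
})

test_that("variability-learning association bundles the three statistics", {
  set.seed(31)
  n <- 30
  sigma <- runif(n, 1, 6)
  d <- data.frame(early_sd = sigma + rnorm(n, 0, 0.5),
                  early_improvement = 10 + 2 * sigma + rnorm(n),
                  learning_rate = 0.1 + 0.04 * sigma + rnorm(n, 0, 0.02))
  res <- variability_learning_association(d)
  expect_equal(res$r_learning$estimate, cor(d$early_sd, d$learning_rate))
  expect_equal(res$partial$estimate,
               oracle_partial_r(d$early_sd, d$learning_rate,
                                d$early_improvement),
               tolerance = 1e-12)
  expect_gt(res$partial$estimate, 0)
  expect_error(variability_learning_association(d[1:3, ]), "at least 4")
})
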