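#' Per-block behavioural summaries
#'
#' Computes, for every subject/task/block of a preprocessed trial table:
#' the mean angular error, the early mean and SD (first 5 trials by original
#' trial index), the late mean (last 5 trials), and early improvement
#' (error on trial 1 minus error on trial 5). Means use post-Hampel values
#' and exclude removed trials, but the early/late windows are always
#' defined by the original trial indices; windows with removed trials are
#' flagged `partial`. Early improvement is `NA` when trial 1 or 5 was
#' removed.
#'
#' @param table a preprocessed trial table (see [preprocess_trials()]).
#' @return a `MetricsTable` data.frame: one row per subject/task/block with
#'   `period`, `block_type`, `n_used`, `mean_error`, `early_mean`,
#'   `late_mean`, `early_sd`, `early_improvement`, `partial`.
#' @examples
#' tab <- simulate_learner(learner_params(), make_schedule(), "curling", seed = 3)
#' head(block_summaries(preprocess_trials(tab)$table))
#' @export
block_summaries <- function(table) {
  check_trial_table(table)
  key <- paste(table$subject_id, table$task, table$block_label, sep = "\r")
  recs <- lapply(split(seq_len(nrow(table)), key), function(rows) {
    rows <- rows[order(table$trial_in_block[rows])]
    tr <- table$trial_in_block[rows]
    err <- table$angular_error_deg[rows]
    n_tr <- max(tr)
    keep <- !table$is_outlier_removed[rows]
    e_keep <- keep & tr <= 5
    l_keep <- keep & tr > n_tr - 5
    e1 <- err[keep & tr == 1]
    e5 <- err[keep & tr == 5]
    data.frame(
      subject_id = table$subject_id[rows[1]], task = table$task[rows[1]],
      block_label = table$block_label[rows[1]],
      period = table$period[rows[1]], block_type = table$block_type[rows[1]],
      n_used = sum(keep),
      mean_error = mean(err[keep]),
      early_mean = mean(err[e_keep]),
      late_mean = mean(err[l_keep]),
      early_sd = sd(err[e_keep]),
      early_improvement = if (length(e1) == 1 && length(e5) == 1) e1 - e5 else NA_real_,
      partial = sum(e_keep) < 5 || sum(l_keep) < 5,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$subject_id, out$task, out$block_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach block-wise learning rates to a metrics table
#'
#' @param metrics a [block_summaries()] table.
#' @param fits a [fit_blocks()] record table.
#' @return `metrics` with a `learning_rate` column (`B_hat`; `NA` for
#'   blocks without a fit).
#' @export
add_learning_rates <- function(metrics, fits) {
  m <- merge(metrics,
             fits[, c("subject_id", "task", "block_label", "B_hat")],
             by = c("subject_id", "task", "block_label"), all.x = TRUE)
  names(m)[names(m) == "B_hat"] <- "learning_rate"
  m
}

#' Savings curve: early performance across successive adaptation blocks
#'
#' Savings (faster relearning on re-exposure) shows as a decrease of the
#' first-five-trials mean error over successive adaptation blocks of the
#' learning period.
#'
#' @param metrics a [block_summaries()] table.
#' @param period experimental period to use (default `"learning"`).
#' @return list of class `vmr_savings` with `by_subject` (subject x block
#'   `early_mean` values, in block order), `curve` (across-subject mean
#'   early error per task and block) and `diffs` (per-subject differences
#'   between consecutive adaptation blocks, summarised with a paired t
#'   test).
#' @export
savings_curve <- function(metrics, period = "learning") {
  ad <- metrics[metrics$block_type == "adaptation" & metrics$period == period, ]
  blocks <- unique(ad$block_label)
  if (length(blocks) < 2L) stopf("need at least 2 adaptation blocks")
  ad$block_label <- factor(ad$block_label, levels = blocks)
  curve <- aggregate(early_mean ~ task + block_label, data = ad, FUN = mean)
  diffs <- list()
  for (task in unique(ad$task)) {
    sub <- ad[ad$task == task, ]
    wide <- tapply(sub$early_mean, list(sub$subject_id, sub$block_label), mean)
    for (j in seq_len(ncol(wide) - 1L)) {
      d <- wide[, j] - wide[, j + 1L]
      d <- d[!is.na(d)]
      tt <- if (length(d) >= 2 && sd(d) > 0) t.test(d) else NULL
      diffs[[paste(task, colnames(wide)[j], colnames(wide)[j + 1L], sep = "_")]] <-
        data.frame(task = task,
                   from = colnames(wide)[j], to = colnames(wide)[j + 1L],
                   mean_diff = mean(d),
                   t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                   p = if (is.null(tt)) NA_real_ else tt$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  diffs <- do.call(rbind, diffs)
  rownames(diffs) <- NULL
  structure(list(by_subject = ad[, c("subject_id", "task", "block_label",
                                     "early_mean")],
                 curve = curve, diffs = diffs),
            class = "vmr_savings")
}

#' @export
print.vmr_savings <- function(x, ...) {
  cat("Savings curve (mean early error per adaptation block):\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Retention contrast: last learning vs first retention adaptation block
#'
#' Compares each subject's mean angular error in the final adaptation block
#' of the learning period against the first adaptation block of the
#' retention period with a paired t test (per task). Positive differences
#' (learning minus retention) indicate retained adaptation after the break.
#'
#' @param metrics a [block_summaries()] table covering both blocks for every
#'   subject.
#' @return data.frame per task: `n`, `mean_diff`, `t`, `df`, `p`.
#' @export
retention_contrast <- function(metrics) {
  out <- list()
  for (task in unique(metrics$task)) {
    m <- metrics[metrics$task == task, ]
    last_ad <- tail(unique(m$block_label[m$block_type == "adaptation" &
                                           m$period == "learning"]), 1)
    first_ret <- head(unique(m$block_label[m$block_type == "adaptation" &
                                             m$period == "retention"]), 1)
    if (!length(last_ad) || !length(first_ret)) {
      stopf("task %s lacks a learning or retention adaptation block", task)
    }
    a <- m[m$block_label == last_ad, c("subject_id", "mean_error")]
    b <- m[m$block_label == first_ret, c("subject_id", "mean_error")]
    if (!setequal(a$subject_id, b$subject_id)) {
      stopf("task %s: subjects missing one of the contrasted blocks", task)
    }
    b <- b[match(a$subject_id, b$subject_id), ]
    d <- a$mean_error - b$mean_error
    if (length(d) >= 2 && sd(d) > 0) {
      tt <- t.test(d)
      out[[task]] <- data.frame(task = task, n = length(d),
                                mean_diff = mean(d),
                                t = unname(tt$statistic),
                                df = unname(tt$parameter), p = tt$p.value,
                                stringsAsFactors = FALSE)
    } else {
      out[[task]] <- data.frame(task = task, n = length(d),
                                mean_diff = mean(d), t = 0,
                                df = length(d) - 1, p = 1,
                                stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Washout aftereffect: change from baseline to washout
#'
#' Computes each subject's change in mean absolute angular error from the
#' baseline block to the washout block (washout minus baseline; positive
#' values indicate an aftereffect) and, when both tasks are present,
#' contrasts the change across tasks with a paired t test.
#'
#' @param table a preprocessed trial table containing baseline and washout
#'   blocks.
#' @return list with `by_subject` (per subject/task change) and
#'   `task_contrast` (paired t test across tasks, `NULL` if only one task).
#' @export
washout_change <- function(table) {
  check_trial_table(table)
  keep <- !table$is_outlier_removed
  base <- table[keep & table$block_type == "baseline", ]
  wash <- table[keep & table$block_type == "washout", ]
  if (!nrow(base) || !nrow(wash)) stopf("baseline and washout blocks required")
  bm <- aggregate(angular_error_deg ~ subject_id + task, data = base,
                  FUN = function(e) mean(abs(e)))
  wm <- aggregate(angular_error_deg ~ subject_id + task, data = wash,
                  FUN = function(e) mean(abs(e)))
  names(bm)[3] <- "baseline_mean"
  names(wm)[3] <- "washout_mean"
  by_subject <- merge(bm, wm, by = c("subject_id", "task"))
  by_subject$change <- by_subject$washout_mean - by_subject$baseline_mean

  task_contrast <- NULL
  tasks <- unique(by_subject$task)
  if (length(tasks) == 2L) {
    w <- merge(by_subject[by_subject$task == tasks[1], c("subject_id", "change")],
               by_subject[by_subject$task == tasks[2], c("subject_id", "change")],
               by = "subject_id")
    d <- w$change.x - w$change.y
    if (length(d) >= 2 && sd(d) > 0) {
      tt <- t.test(d)
      task_contrast <- data.frame(task_a = tasks[1], task_b = tasks[2],
                                  n = length(d), mean_diff = mean(d),
                                  t = unname(tt$statistic),
                                  df = unname(tt$parameter), p = tt$p.value,
                                  stringsAsFactors = FALSE)
    }
  }
  list(by_subject = by_subject, task_contrast = task_contrast)
}

#' Reinforcement-condition contrasts with FDR-corrected follow-ups
#'
#' Tests a subject-level measure for a between-subject effect of
#' reinforcement condition: a one-way ANOVA F test (equal-variance) across
#' conditions followed by pairwise two-sample t tests with
#' Benjamini-Hochberg adjustment of the p-values.
#'
#' @param data data.frame with one row per subject, containing a
#'   `condition` column and the measure column.
#' @param measure name of the measure column (default `"mean_error"`).
#' @return list of class `vmr_condition_contrasts` with `anova` (`F`,
#'   `df1`, `df2`, `p`) and `pairwise` (per pair: `t`, `df`, `p`,
#'   `p_adj`).
#' @examples
#' d <- data.frame(condition = rep(c("neutral", "reward"), each = 5),
#'                 mean_error = c(rnorm(5, 10), rnorm(5, 8)))
#' condition_contrasts(d)
#' @export
condition_contrasts <- function(data, measure = "mean_error") {
  if (!all(c("condition", measure) %in% names(data))) {
    stopf("data needs columns 'condition' and '%s'", measure)
  }
  v <- data[[measure]]
  cond <- as.factor(data$condition)
  counts <- table(cond)
  if (length(counts) < 2L) stopf("need at least 2 conditions")
  if (any(counts < 2L)) {
    stopf("condition(s) with fewer than 2 subjects: %s",
          paste(names(counts)[counts < 2], collapse = ", "))
  }
  if (sd(v) == 0) {
    ow <- list(statistic = c(F = 0),
               parameter = c(`num df` = length(counts) - 1L,
                             `denom df` = length(v) - length(counts)),
               p.value = 1)
  } else {
    ow <- oneway.test(v ~ cond, var.equal = TRUE)
  }
  an <- data.frame(F = unname(ow$statistic),
                   df1 = unname(ow$parameter[1]),
                   df2 = unname(ow$parameter[2]),
                   p = ow$p.value)

  pairs <- combn(levels(cond), 2, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    x <- v[cond == pr[1]]
    y <- v[cond == pr[2]]
    if (sd(c(x, y)) == 0) {
      data.frame(a = pr[1], b = pr[2], mean_diff = 0, t = 0,
                 df = length(x) + length(y) - 2L, p = 1,
                 stringsAsFactors = FALSE)
    } else {
      tt <- t.test(x, y, var.equal = TRUE)
      data.frame(a = pr[1], b = pr[2], mean_diff = mean(x) - mean(y),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }
  })
  pw <- do.call(rbind, pw)
  pw$p_adj <- p.adjust(pw$p, method = "BH")
  structure(list(measure = measure, anova = an, pairwise = pw),
            class = "vmr_condition_contrasts")
}

#' @export
print.vmr_condition_contrasts <- function(x, ...) {
  cat(sprintf("One-way condition effect on %s: F(%g, %g) = %.3f, p = %.4g\n",
              x$measure, x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  cat("Pairwise t tests (BH-adjusted):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' First-order partial correlation
#'
#' Pearson correlation between `x` and `y` after removing the linear
#' contribution of a single control variable `z`:
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#' The two-sided p-value uses the t transform with `n - 3` degrees of
#' freedom.
#'
#' @param x,y,z equal-length numeric vectors (n >= 4), no missing values.
#' @return list with `estimate`, `statistic` (t), `df`, `p_value`, `n`.
#' @examples
#' set.seed(1)
#' z <- rnorm(30); x <- z + rnorm(30); y <- z + rnorm(30)
#' partial_correlation(x, y, z)$estimate
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stopf("x, y, z must have equal length")
  if (n < 4L) stopf("need at least 4 paired observations")
  if (anyNA(x) || anyNA(y) || anyNA(z)) stopf("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0) {
    stopf("zero variance: partial correlation undefined")
  }
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  denom <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (denom == 0) stopf("control variable is collinear with x or y")
  r <- (rxy - rxz * ryz) / denom
  df <- n - 3L
  tstat <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  list(estimate = r, statistic = tstat, df = df,
       p_value = 2 * pt(-abs(tstat), df), n = n)
}

#' Association between early variability and learning
#'
#' Correlates subject-level early motor variability (`early_sd`) with (i)
#' early improvement and (ii) the model-based learning rate, and computes
#' the partial correlation between early variability and learning rate
#' controlling for early improvement. When early variability reflects
#' exploratory planning noise, it remains positively associated with the
#' learning rate even after early improvement is partialled out.
#'
#' @param data data.frame with one row per subject and columns `early_sd`,
#'   `early_improvement`, `learning_rate` (no missing values; n >= 4).
#' @return list of class `vmr_variability_assoc` with `r_improvement`,
#'   `r_learning` (each: estimate, p) and `partial` (see
#'   [partial_correlation()]).
#' @export
variability_learning_association <- function(data) {
  need <- c("early_sd", "early_improvement", "learning_rate")
  if (!all(need %in% names(data))) {
    stopf("data needs columns: %s", paste(need, collapse = ", "))
  }
  d <- data[, need]
  if (anyNA(d)) stopf("missing values not allowed")
  if (nrow(d) < 4L) stopf("need at least 4 paired observations")
  if (any(vapply(d, sd, numeric(1)) == 0)) {
    stopf("zero variance in a variable: correlations undefined")
  }
  c1 <- cor.test(d$early_sd, d$early_improvement)
  c2 <- cor.test(d$early_sd, d$learning_rate)
  structure(list(
    n = nrow(d),
    r_improvement = list(estimate = unname(c1$estimate), p = c1$p.value),
    r_learning = list(estimate = unname(c2$estimate), p = c2$p.value),
    partial = partial_correlation(d$early_sd, d$learning_rate,
                                  d$early_improvement)
  ), class = "vmr_variability_assoc")
}

#' @export
print.vmr_variability_assoc <- function(x, ...) {
  cat(sprintf("Early variability vs early improvement: r = %.3f (p = %.4g)\n",
              x$r_improvement$estimate, x$r_improvement$p))
  cat(sprintf("Early variability vs learning rate:     r = %.3f (p = %.4g)\n",
              x$r_learning$estimate, x$r_learning$p))
  cat(sprintf("Partial (controlling early improvement): r = %.3f (p = %.4g, n = %d)\n",
              x$partial$estimate, x$partial$p_value, x$n))
  invisible(x)
}
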