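#' Flag extreme angular-error outliers
#'
#' Trials whose absolute angular error exceeds `cutoff_deg` (default 60
#' degrees, i.e. half again the rotation magnitude) are flagged for removal;
#' the order of the remaining trials is preserved and no replacement is
#' attempted. The rule is idempotent.
#'
#' @param x numeric vector of angular errors, degrees.
#' @param cutoff_deg absolute-error cutoff, degrees.
#' @return list with `x` (the input, unchanged) and `flag` (logical,
#'   `TRUE` where the trial is an extreme outlier).
#' @examples
#' remove_extreme_outliers(c(10, 65, -70, 5))$flag
#' @export
remove_extreme_outliers <- function(x, cutoff_deg = 60) {
  if (!is.numeric(x)) stopf("x must be numeric")
  if (any(!is.finite(x))) stopf("errors must be finite")
  list(x = x, flag = abs(x) > cutoff_deg)
}

#' Sliding-window Hampel filter for trial series
#'
#' Identifies and replaces outliers against the median of a sliding window
#' of the 6 nearest neighbours (3 on each side, truncated at the series
#' ends, centre excluded). A point is replaced by its neighbourhood median
#' when it deviates from that median by more than `n_sigmas` scaled median
#' absolute deviations (MAD x 1.4826). When the window MAD is zero, any
#' deviation from the median is replaced. The first `protect_first` points
#' of the series are never replaced — early adaptation trials carry genuine
#' large errors — but they do serve as neighbours for later points. The
#' filter makes a single pass over the original values: replacements never
#' feed back into later windows.
#'
#' @param x numeric vector (a within-block trial series), length >= 2.
#' @param window number of neighbours in the window (default 6, i.e. 3 per
#'   side); must be an even number >= 2.
#' @param n_sigmas deviation threshold in scaled-MAD units.
#' @param protect_first number of leading points never replaced.
#' @return list with `x` (the filtered series) and `flag` (logical, `TRUE`
#'   where a value was replaced).
#' @examples
#' hampel_filter(c(0, 0, 0, 0, 0, 0, 50, 0, 0, 0))$x
#' @export
hampel_filter <- function(x, window = 6, n_sigmas = 3, protect_first = 5) {
  if (!is.numeric(x) || length(x) < 2L) stopf("x must be numeric, length >= 2")
  if (!is_number(window) || window < 2 || window %% 2 != 0) {
    stopf("window must be an even number >= 2")
  }
  half <- window %/% 2
  n <- length(x)
  out <- x
  flag <- logical(n)
  start <- protect_first + 1L
  if (start > n) return(list(x = out, flag = flag))
  # median of a small sorted window, avoiding S3 dispatch in the hot loop
  fast_median <- function(v) {
    s <- sort.int(v, method = "quick")
    m <- length(s)
    if (m %% 2L == 1L) s[(m + 1L) %/% 2L] else (s[m %/% 2L] + s[m %/% 2L + 1L]) / 2
  }
  for (i in start:n) {
    nb <- x[max(1L, i - half):min(n, i + half)][-(i - max(1L, i - half) + 1L)]
    med <- fast_median(nb)
    scaled_mad <- 1.4826 * fast_median(abs(nb - med))
    replace <- if (scaled_mad > 0) {
      abs(x[i] - med) > n_sigmas * scaled_mad
    } else {
      x[i] != med
    }
    if (replace) {
      out[i] <- med
      flag[i] <- TRUE
    }
  }
  list(x = out, flag = flag)
}

#' Preprocess a trial table (extreme removal, then Hampel filtering)
#'
#' Applies [remove_extreme_outliers()] and then [hampel_filter()] to each
#' subject/task/block series, in that order: extreme outliers are flagged
#' `is_outlier_removed` and excluded before the Hampel pass, which operates
#' on the surviving trials of the block (protecting its first
#' `protect_first` surviving trials) and writes replaced values back into
#' `angular_error_deg` with `is_hampel_replaced = TRUE`.
#'
#' @param table a trial table (see [simulate_learner()] /
#'   [read_trial_table()]).
#' @param cutoff_deg extreme-outlier cutoff, degrees.
#' @param window,n_sigmas,protect_first Hampel parameters, see
#'   [hampel_filter()].
#' @param hampel set `FALSE` to skip the Hampel pass (extreme removal only).
#' @return list of class `vmr_preprocess` with `table` (the preprocessed
#'   trial table) and `report` (a `vmr_preprocess_report`: counts, percent
#'   flagged, per-subject and per-task breakdown).
#' @examples
#' tab <- simulate_learner(learner_params(), make_schedule(), "curling", seed = 1)
#' pp <- preprocess_trials(tab)
#' pp$report
#' @export
preprocess_trials <- function(table, cutoff_deg = 60, window = 6,
                              n_sigmas = 3, protect_first = 5,
                              hampel = TRUE) {
  check_trial_table(table)
  table$is_outlier_removed <- FALSE
  table$is_hampel_replaced <- FALSE
  key <- paste(table$subject_id, table$task, table$block_label, sep = "\r")
  for (rows in split(seq_len(nrow(table)), key)) {
    rows <- rows[order(table$trial_in_block[rows])]
    ext <- remove_extreme_outliers(table$angular_error_deg[rows], cutoff_deg)
    table$is_outlier_removed[rows] <- ext$flag
    if (hampel) {
      keep <- rows[!ext$flag]
      if (length(keep) >= 2L) {
        hf <- hampel_filter(table$angular_error_deg[keep], window = window,
                            n_sigmas = n_sigmas,
                            protect_first = protect_first)
        table$angular_error_deg[keep] <- hf$x
        table$is_hampel_replaced[keep] <- hf$flag
      }
    }
  }
  report <- preprocess_report(table)
  structure(list(table = table, report = report), class = "vmr_preprocess")
}

preprocess_report <- function(table) {
  n <- nrow(table)
  n_removed <- sum(table$is_outlier_removed)
  n_replaced <- sum(table$is_hampel_replaced)
  flagged <- table$is_outlier_removed | table$is_hampel_replaced
  by_subject <- aggregate(flagged ~ subject_id + task, data = table,
                          FUN = function(f) sum(f))
  names(by_subject)[3] <- "n_flagged"
  by_task <- aggregate(flagged ~ task, data = table, FUN = mean)
  names(by_task)[2] <- "pct_flagged"
  by_task$pct_flagged <- 100 * by_task$pct_flagged
  structure(list(
    n_trials = n,
    n_removed_extreme = n_removed,
    n_replaced_hampel = n_replaced,
    pct_outliers = 100 * (n_removed + n_replaced) / n,
    by_subject = by_subject,
    by_task = by_task
  ), class = "vmr_preprocess_report")
}

#' @export
print.vmr_preprocess_report <- function(x, ...) {
  cat(sprintf(
    "Preprocessing: %d trials; %d removed (extreme), %d replaced (Hampel); %.2f%% flagged\n",
    x$n_trials, x$n_removed_extreme, x$n_replaced_hampel, x$pct_outliers))
  print(x$by_task, row.names = FALSE)
  invisible(x)
}

#' Log-standardise a series of angular errors to a baseline median
#'
#' \eqn{s_n = \log_{10}(\max(|e_n|, \epsilon)) -
#'   \log_{10}(\max(m, \epsilon))}, where `m` is the baseline median
#' absolute error and the floor \eqn{\epsilon} (default 0.5 degrees) guards
#' the logarithm against zero errors. The transform removes
#' between-subject differences in error range before model fitting and is
#' invariant to a common positive rescaling of the errors and the baseline
#' median (above the floor).
#'
#' @param e numeric vector of angular errors, degrees.
#' @param baseline_median median absolute baseline error, degrees.
#' @param eps floor applied inside the logarithm, degrees.
#' @return numeric vector of standardised (decimal-log) errors.
#' @examples
#' standardise_series(c(40, 4), baseline_median = 4)
#' @export
standardise_series <- function(e, baseline_median, eps = 0.5) {
  if (!is_number(baseline_median) || baseline_median < 0) {
    stopf("baseline_median must be a single non-negative number")
  }
  log10(pmax(abs(e), eps)) - log10(max(baseline_median, eps))
}

#' Standardise adaptation trials of a table to baseline performance
#'
#' For each subject/task, computes the median absolute error of the
#' surviving baseline-block trials and log-standardises the surviving
#' rotated (adaptation-block) trials to it via [standardise_series()]. The
#' rotation magnitude is transformed consistently:
#' \eqn{r' = \log_{10}(r) - \log_{10}(\max(m, \epsilon))}.
#'
#' @inheritParams preprocess_trials
#' @param eps floor inside the logarithm, degrees.
#' @return a data.frame of the surviving adaptation-block trials with extra
#'   columns `std_error` (standardised error), `std_rotation` (transformed
#'   rotation) and `baseline_median`.
#' @export
standardise_to_baseline <- function(table, eps = 0.5) {
  check_trial_table(table)
  keep <- !table$is_outlier_removed
  out <- list()
  for (sid in unique(table$subject_id)) {
    for (task in unique(table$task[table$subject_id == sid])) {
      sel <- table$subject_id == sid & table$task == task & keep
      base <- table[sel & table$block_type == "baseline", ]
      if (!nrow(base)) {
        stopf("missing baseline block for subject %s, task %s", sid, task)
      }
      m <- median(abs(base$angular_error_deg))
      ad <- table[sel & table$block_type == "adaptation", ]
      if (!nrow(ad)) next
      ad$std_error <- standardise_series(ad$angular_error_deg, m, eps)
      ad$std_rotation <- log10(pmax(abs(ad$rotation_deg), eps)) -
        log10(max(m, eps))
      ad$baseline_median <- m
      out[[paste(sid, task)]] <- ad
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
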