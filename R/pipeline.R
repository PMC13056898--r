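#' Run the full adaptation-analysis pipeline
#'
#' Executes the stages end to end: obtain a trial table (read
#' `config$paths$input_table`, or simulate the configured cohort),
#' preprocess (extreme removal then Hampel filtering), fit the state-space
#' model block-wise, compute behavioural metrics and contrasts, and write
#' every artefact plus a manifest to the output directory. The run is
#' deterministic given the seed: re-running with the same configuration and
#' seed produces byte-identical outputs.
#'
#' Artefacts written to `out_dir`:
#' \describe{
#'   \item{trials_preprocessed.csv}{the flagged/filtered trial table}
#'   \item{preprocess_report.json}{outlier counts and percentages}
#'   \item{statespace_fits.csv}{per subject/task/block fit records}
#'   \item{metrics.csv}{block summaries with learning rates}
#'   \item{analysis_report.json}{condition contrasts, retention, washout and
#'     variability-learning associations per task}
#'   \item{manifest.json}{seed, full parameter set and MD5 of each artefact}
#' }
#'
#' @param config a [pipeline_config()] (or a path to a YAML/JSON config
#'   file).
#' @param out_dir output directory; overrides `config$paths$out_dir`.
#' @param seed seed; overrides `config$seed`.
#' @return (invisibly) a list with the in-memory `trials`, `fits`,
#'   `metrics`, `report` and the `out_dir`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(cohort = list(n_per_condition = 2), seed = 1,
#'                        verbose = FALSE)
#' res <- run_pipeline(cfg, out_dir = tempfile())
#' names(res)
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "vmr_pipeline_config")) {
    stopf("config must be a vmr_pipeline_config or a config file path")
  }
  seed <- seed %||% config$seed
  out_dir <- out_dir %||% config$paths$out_dir
  if (is.null(out_dir)) stopf("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (config$verbose) message(sprintf(...))

  if (!is.null(config$paths$input_table)) {
    trials <- read_trial_table(config$paths$input_table)
    log_msg("stage input: read %d trials from %s", nrow(trials),
            config$paths$input_table)
  } else {
    trials <- simulate_cohort(config$cohort, make_schedule(), seed = seed)
    log_msg("stage simulate: %d trials, %d subjects", nrow(trials),
            length(unique(trials$subject_id)))
  }

  pp <- config$preprocessing
  pre <- preprocess_trials(trials, cutoff_deg = pp$cutoff_deg,
                           window = pp$window, n_sigmas = pp$n_sigmas,
                           protect_first = pp$protect_first,
                           hampel = pp$hampel)
  log_msg("stage preprocess: %d removed, %d replaced (%.2f%% flagged)",
          pre$report$n_removed_extreme, pre$report$n_replaced_hampel,
          pre$report$pct_outliers)
  write_trial_table(pre$table, file.path(out_dir, "trials_preprocessed.csv"))
  jsonlite::write_json(
    list(n_trials = pre$report$n_trials,
         n_removed_extreme = pre$report$n_removed_extreme,
         n_replaced_hampel = pre$report$n_replaced_hampel,
         pct_outliers = pre$report$pct_outliers,
         by_task = pre$report$by_task),
    file.path(out_dir, "preprocess_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  fits <- fit_blocks(pre$table, scale = config$fit$scale, eps = pp$eps,
                     starts = config$fit$starts, tol = config$fit$tol)
  log_msg("stage fit: %d blocks, %d converged", nrow(fits),
          sum(fits$converged))
  write.csv(fits, file.path(out_dir, "statespace_fits.csv"),
            row.names = FALSE)

  metrics <- add_learning_rates(block_summaries(pre$table), fits)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)

  report <- analysis_report(pre$table, metrics)
  jsonlite::write_json(report, file.path(out_dir, "analysis_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("stage metrics: report written")

  artefacts <- c("trials_preprocessed.csv", "preprocess_report.json",
                 "statespace_fits.csv", "metrics.csv", "analysis_report.json")
  manifest <- list(
    seed = seed,
    parameters = list(preprocessing = config$preprocessing,
                      fit = config$fit[c("scale", "tol")],
                      fit_starts = config$fit$starts,
                      cohort = unclass(config$cohort)),
    md5 = as.list(tools::md5sum(file.path(out_dir, artefacts)))
  )
  names(manifest$md5) <- artefacts
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(trials = pre$table, fits = fits, metrics = metrics,
                 report = report, out_dir = out_dir))
}

#' Subject-level summary used by the cohort contrasts
#'
#' One row per subject/task: mean error over the learning-period adaptation
#' blocks, the across-block means of early SD and early improvement, and
#' the mean block-wise learning rate.
#'
#' @param metrics a [block_summaries()] table with a `learning_rate` column
#'   (see [add_learning_rates()]).
#' @param table optional trial table used to attach each subject's
#'   reinforcement condition.
#' @return data.frame with columns `subject_id`, `task`, `condition` (if
#'   `table` is given), `mean_error`, `early_sd`, `early_improvement`,
#'   `learning_rate`.
#' @export
subject_summaries <- function(metrics, table = NULL) {
  ad <- metrics[metrics$block_type == "adaptation" &
                  metrics$period == "learning", ]
  agg <- aggregate(cbind(mean_error, early_sd, early_improvement,
                         learning_rate) ~ subject_id + task,
                   data = ad, FUN = mean, na.action = stats::na.omit)
  if (!is.null(table)) {
    cond <- unique(table[, c("subject_id", "condition")])
    agg <- merge(agg, cond, by = "subject_id")
  }
  agg
}

# Full cohort analysis block: per-task condition contrasts on mean
# adaptation error, retention and washout contrasts, and the
# variability-learning association.
analysis_report <- function(table, metrics) {
  subj <- subject_summaries(metrics, table)
  per_task <- list()
  for (task in sort(unique(subj$task))) {
    st <- subj[subj$task == task, ]
    entry <- list()
    if (length(unique(st$condition)) >= 2 && min(table(st$condition)) >= 2) {
      cc <- condition_contrasts(st, "mean_error")
      entry$condition_anova <- cc$anova
      entry$condition_pairwise <- cc$pairwise
    }
    if (nrow(st) >= 4) {
      va <- variability_learning_association(st)
      entry$variability <- list(
        r_improvement = va$r_improvement, r_learning = va$r_learning,
        partial_r = va$partial$estimate, partial_p = va$partial$p_value)
    }
    per_task[[task]] <- entry
  }
  ret <- retention_contrast(metrics)
  wo <- washout_change(table)
  list(tasks = per_task, retention = ret,
       washout = list(task_contrast = wo$task_contrast,
                      mean_change = aggregate(change ~ task,
                                              data = wo$by_subject,
                                              FUN = mean)))
}
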