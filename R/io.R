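# Canonical trial-table schema (column order of the CSV interface).
TRIAL_TABLE_COLUMNS <- c(
  "subject_id", "task", "condition", "period", "block_label", "block_type",
  "trial_in_block", "rotation_deg", "angular_error_deg", "points_awarded",
  "is_outlier_removed", "is_hampel_replaced"
)

check_trial_table <- function(table) {
  if (!is.data.frame(table)) stopf("trial table must be a data.frame")
  missing <- setdiff(TRIAL_TABLE_COLUMNS, names(table))
  if (length(missing)) {
    stopf("trial table is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  invisible(table)
}

#' Write a trial table to CSV
#'
#' Writes the canonical 12-column long-format CSV (header row, UTF-8).
#' Missing `points_awarded` values are written as empty fields; in-memory
#' extras such as `planned_error_deg` are dropped.
#'
#' @param table a trial table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  check_trial_table(table)
  write.csv(table[, TRIAL_TABLE_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Validates the canonical schema: all required columns present, numeric
#' fields numeric (malformed rows reported with line numbers), and no
#' duplicate (subject, task, block, trial) keys.
#'
#' @param path CSV file path.
#' @return a trial table data.frame.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = character())
  missing <- setdiff(TRIAL_TABLE_COLUMNS, names(raw))
  if (length(missing)) {
    stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  }
  num_cols <- c("trial_in_block", "rotation_deg", "angular_error_deg")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(raw[[col]]) | !nzchar(raw[[col]]))
    if (length(bad)) {
      stopf("non-numeric %s at line(s): %s", col,
            paste(bad + 1L, collapse = ", "))  # +1 for the header row
    }
    raw[[col]] <- v
  }
  pa <- raw$points_awarded
  v <- suppressWarnings(as.numeric(pa))
  bad <- which(is.na(v) & nzchar(pa))
  if (length(bad)) {
    stopf("non-numeric points_awarded at line(s): %s",
          paste(bad + 1L, collapse = ", "))
  }
  raw$points_awarded <- as.integer(v)
  for (col in c("is_outlier_removed", "is_hampel_replaced")) {
    raw[[col]] <- as.logical(raw[[col]])
    if (anyNA(raw[[col]])) stopf("column %s must be TRUE/FALSE", col)
  }
  raw$trial_in_block <- as.integer(raw$trial_in_block)
  key <- paste(raw$subject_id, raw$task, raw$block_label, raw$trial_in_block)
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stopf("duplicate trial key(s): %s",
          paste(unique(dup)[seq_len(min(3, length(unique(dup))))],
                collapse = "; "))
  }
  raw[, TRIAL_TABLE_COLUMNS]
}

#' Write trajectories as per-trial CSV files with JSON sidecars
#'
#' Each trajectory is written as `<subject>/<task>/<block>/trial<k>.csv`
#' (columns `t_ms`, `x_mm`, `y_mm`) with a JSON sidecar carrying the start
#' and target coordinates, the task tag and the release radius.
#'
#' @param trajs list of [vmr_trajectory()] objects.
#' @param dir output directory (created if needed).
#' @return character vector of CSV paths, invisibly.
#' @export
write_trajectories <- function(trajs, dir) {
  paths <- character(length(trajs))
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    m <- tr$meta
    sub_dir <- file.path(dir, m$subject_id %||% "S01", tr$task,
                         m$block_label %||% "B1")
    dir.create(sub_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(sub_dir, sprintf("trial%03d", m$trial_in_block %||% i))
    write.csv(data.frame(t_ms = tr$t_ms, x_mm = tr$x_mm, y_mm = tr$y_mm),
              paste0(stem, ".csv"), row.names = FALSE)
    jsonlite::write_json(
      list(start_xy = tr$start_xy, target_xy = tr$target_xy, task = tr$task,
           release_radius_mm = tr$release_radius_mm, meta = m),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
    paths[i] <- paste0(stem, ".csv")
  }
  invisible(paths)
}

#' Read one trajectory written by [write_trajectories()]
#'
#' @param csv_path path to the per-trial CSV; the JSON sidecar is expected
#'   alongside it.
#' @return a [vmr_trajectory()] object.
#' @export
read_trajectory <- function(csv_path) {
  side <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(csv_path) || !file.exists(side)) {
    stopf("trajectory CSV or JSON sidecar not found for %s", csv_path)
  }
  d <- read.csv(csv_path)
  j <- jsonlite::read_json(side, simplifyVector = TRUE)
  vmr_trajectory(d$t_ms, d$x_mm, d$y_mm, j$start_xy, j$target_xy,
                 task = j$task, release_radius_mm = j$release_radius_mm,
                 meta = as.list(j$meta))
}

#' Read a pipeline configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) file mirroring the
#' [pipeline_config()] fields and validates it (unknown keys are rejected).
#'
#' @param path configuration file path.
#' @return a `vmr_pipeline_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stopf("unsupported config format: .%s (use YAML or JSON)", ext)
  )
  do.call(pipeline_config, raw)
}

#' Construct a validated pipeline configuration
#'
#' Bundles every tunable stage parameter with its default: the
#' extreme-outlier cutoff (60 deg), Hampel window (6 neighbours), threshold
#' (3 scaled MADs) and protected prefix (5 trials), the log floor
#' (0.5 deg), the fit scale and optimiser starts, the cohort configuration
#' used when simulating, and the seed.
#'
#' @param paths list with optional `input_table` (CSV to analyse instead of
#'   simulating) and `out_dir`.
#' @param cohort a [cohort_config()] or a named list of its arguments.
#' @param preprocessing named list overriding `cutoff_deg`, `window`,
#'   `n_sigmas`, `protect_first`, `eps`, `hampel`.
#' @param fit named list overriding `scale` (`"standardised"` or
#'   `"raw_degrees"`), `starts`, `tol`.
#' @param seed integer seed for the whole run.
#' @param verbose emit per-stage progress messages.
#' @return a `vmr_pipeline_config` object.
#' @export
pipeline_config <- function(paths = list(), cohort = list(),
                            preprocessing = list(), fit = list(),
                            seed = 1L, verbose = TRUE) {
  check_keys <- function(x, allowed, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stopf("unknown %s key(s): %s", what, paste(bad, collapse = ", "))
    }
  }
  check_keys(paths, c("input_table", "out_dir"), "paths")
  pp_defaults <- list(cutoff_deg = 60, window = 6, n_sigmas = 3,
                      protect_first = 5, eps = 0.5, hampel = TRUE)
  check_keys(preprocessing, names(pp_defaults), "preprocessing")
  pp <- modifyList(pp_defaults, preprocessing)
  if (pp$window < 2) stopf("preprocessing window must be >= 2")
  fit_defaults <- list(scale = "standardised",
                       starts = list(c(0.9, 0.1), c(0.99, 0.3), c(0.5, 0.5)),
                       tol = 1e-9)
  check_keys(fit, names(fit_defaults), "fit")
  ft <- modifyList(fit_defaults, fit)
  if (!ft$scale %in% c("standardised", "raw_degrees")) {
    stopf("fit scale must be 'standardised' or 'raw_degrees'")
  }
  if (!inherits(cohort, "cohort_config")) {
    cohort <- do.call(cohort_config, as.list(cohort))
  }
  structure(list(paths = paths, cohort = cohort, preprocessing = pp,
                 fit = ft, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "vmr_pipeline_config")
}
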