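#' Build a blocked visuomotor-rotation schedule
#'
#' A schedule is an ordered sequence of trial blocks, each labelled with a
#' block type (`baseline`, `adaptation`, `deadaptation`, `washout`) and an
#' experimental period (`learning` or `retention`). Every trial carries the
#' rotation applied on that trial: `rotation_deg` (counterclockwise positive)
#' during adaptation blocks and 0 elsewhere.
#'
#' The default design is the two-period layout used throughout the package:
#' a Learning period of 400 trials (baseline block, then adaptation and
#' de-adaptation blocks alternating, ending on the fifth adaptation block)
#' and, after a break, a Retention period of 160 trials (adaptation,
#' de-adaptation, adaptation, washout), all in blocks of 40 trials with a
#' 40 degree counterclockwise rotation during adaptation.
#'
#' @param design either the string `"paper-default"` for the layout above, or
#'   a data.frame with columns `block_label`, `period`
#'   (`"learning"`/`"retention"`), `block_type` (`"baseline"`,
#'   `"adaptation"`, `"deadaptation"`, `"washout"`) and `n_trials`.
#' @param rotation_deg rotation magnitude applied during adaptation blocks,
#'   degrees counterclockwise.
#' @return an object of class `vmr_schedule`: a list with `blocks` (the
#'   block-level design) and `trials` (one row per trial: `block_index`,
#'   `block_label`, `period`, `block_type`, `trial_in_block`, `rotation_deg`,
#'   and `adapt_block_num`, the ordinal position among adaptation blocks,
#'   `NA` elsewhere).
#' @examples
#' sched <- make_schedule()
#' sched
#' table(sched$trials$rotation_deg)
#' @export
make_schedule <- function(design = "paper-default", rotation_deg = 40) {
  if (!is_number(rotation_deg)) stopf("rotation_deg must be a finite number")
  if (identical(design, "paper-default")) {
    design <- default_design()
  }
  if (!is.data.frame(design)) {
    stopf("design must be \"paper-default\" or a data.frame of blocks")
  }
  required <- c("block_label", "period", "block_type", "n_trials")
  missing <- setdiff(required, names(design))
  if (length(missing)) {
    stopf("design is missing column(s): %s", paste(missing, collapse = ", "))
  }
  types <- c("baseline", "adaptation", "deadaptation", "washout")
  bad <- setdiff(unique(design$block_type), types)
  if (length(bad)) stopf("unknown block_type: %s", paste(bad, collapse = ", "))
  bad_p <- setdiff(unique(design$period), c("learning", "retention"))
  if (length(bad_p)) stopf("unknown period: %s", paste(bad_p, collapse = ", "))
  if (any(!is.finite(design$n_trials)) || any(design$n_trials < 1) ||
      any(design$n_trials != round(design$n_trials))) {
    stopf("n_trials must be positive integers")
  }
  if (anyDuplicated(design$block_label)) stopf("block labels must be unique")

  blocks <- data.frame(
    block_index = seq_len(nrow(design)),
    block_label = as.character(design$block_label),
    period = as.character(design$period),
    block_type = as.character(design$block_type),
    n_trials = as.integer(design$n_trials),
    stringsAsFactors = FALSE
  )
  is_ad <- blocks$block_type == "adaptation"
  blocks$adapt_block_num <- NA_integer_
  blocks$adapt_block_num[is_ad] <- seq_len(sum(is_ad))

  idx <- rep(seq_len(nrow(blocks)), blocks$n_trials)
  trials <- data.frame(
    block_index = blocks$block_index[idx],
    block_label = blocks$block_label[idx],
    period = blocks$period[idx],
    block_type = blocks$block_type[idx],
    trial_in_block = unlist(lapply(blocks$n_trials, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  trials$rotation_deg <- ifelse(trials$block_type == "adaptation", rotation_deg, 0)
  trials$adapt_block_num <- blocks$adapt_block_num[idx]

  structure(list(blocks = blocks, trials = trials, rotation_deg = rotation_deg),
            class = "vmr_schedule")
}

default_design <- function() {
  data.frame(
    block_label = c("BL", "Ad1", "DAd1", "Ad2", "DAd2", "Ad3", "DAd3",
                    "Ad4", "DAd4", "Ad5", "Ret1", "DAd5", "Ret2", "Wash"),
    period = c(rep("learning", 10), rep("retention", 4)),
    block_type = c("baseline",
                   rep(c("adaptation", "deadaptation"), 4), "adaptation",
                   "adaptation", "deadaptation", "adaptation", "washout"),
    n_trials = 40L,
    stringsAsFactors = FALSE
  )
}

#' @export
print.vmr_schedule <- function(x, ...) {
  cat("Visuomotor-rotation schedule:", nrow(x$blocks), "blocks,",
      nrow(x$trials), "trials\n")
  cat("Rotation during adaptation blocks:", x$rotation_deg, "deg CCW\n")
  print(x$blocks, row.names = FALSE)
  invisible(x)
}
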