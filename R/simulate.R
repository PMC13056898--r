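#' Simulate one subject's trial series
#'
#' Forward-simulates the single-rate state-space learner through a schedule.
#' On trial \eqn{n} the learner holds an internal estimate \eqn{z_n} of the
#' rotation; the planned (pre-correction) error is
#' \eqn{e^{plan}_n = r_n - z_n + \xi^{plan}_n} and the state update consumes
#' this planned error,
#' \eqn{z_{n+1} = A z_n + B_{eff} e^{plan}_n},
#' so planning noise is visible to between-trial learning. The measured
#' angular error is \eqn{(1-g) e^{plan}_n + \xi^{exec}_n} in reaching (online
#' correction with gain `g`) and \eqn{e^{plan}_n + \xi^{exec}_n} in curling
#' (`g` forced to 0). The effective learning rate in the k-th adaptation
#' block is \eqn{B_{eff} = \min(1, B \cdot savings\_gain^{k-1})}.
#'
#' The state resets to 0 at the start of every adaptation block (the model is
#' also fitted block-wise from \eqn{z_0 = 0}) and carries over into
#' de-adaptation and washout blocks, which therefore show rebound
#' aftereffects.
#'
#' @param params a [learner_params()] object.
#' @param schedule a [make_schedule()] object.
#' @param task `"reaching"` or `"curling"`.
#' @param subject_id,condition identifiers stored in the output table.
#' @param seed optional integer; if given, `set.seed()` is called so the
#'   draw is reproducible. If `NULL` the current RNG stream is used.
#' @return a trial table: one row per trial with columns `subject_id`,
#'   `task`, `condition`, `period`, `block_label`, `block_type`,
#'   `trial_in_block`, `rotation_deg`, `angular_error_deg`, `points_awarded`,
#'   `is_outlier_removed`, `is_hampel_replaced`, plus the in-memory column
#'   `planned_error_deg` (the pre-correction error, used by the trajectory
#'   synthesiser; dropped by [write_trial_table()]).
#' @seealso [simulate_cohort()] for multi-subject cohorts.
#' @examples
#' sched <- make_schedule()
#' p <- learner_params(A = 1, B = 0.5, sigma_plan = 0, sigma_exec = 0)
#' tab <- simulate_learner(p, sched, task = "curling", seed = 1)
#' head(subset(tab, block_label == "Ad1")$angular_error_deg)
#' @export
simulate_learner <- function(params, schedule, task = c("reaching", "curling"),
                             subject_id = "S01", condition = "neutral",
                             seed = NULL) {
  if (!inherits(params, "learner_params")) stopf("params must be learner_params")
  if (!inherits(schedule, "vmr_schedule")) stopf("schedule must be a vmr_schedule")
  task <- match.arg(task)
  condition <- match.arg(condition, c("neutral", "reward", "punishment"))
  if (!is.null(seed)) set.seed(seed)

  g <- if (task == "curling") 0 else params$g
  blocks <- schedule$blocks
  trials <- schedule$trials

  z_carry <- 0
  err <- plan_err <- numeric(nrow(trials))
  for (bi in seq_len(nrow(blocks))) {
    rows <- which(trials$block_index == bi)
    r <- trials$rotation_deg[rows]
    nb <- length(rows)
    is_ad <- blocks$block_type[bi] == "adaptation"
    z0 <- if (is_ad) 0 else z_carry
    B_eff <- if (is_ad) {
      min(1, params$B * params$savings_gain^(blocks$adapt_block_num[bi] - 1))
    } else {
      params$B
    }
    xi_plan <- rnorm(nb, 0, params$sigma_plan)
    xi_exec <- rnorm(nb, 0, params$sigma_exec)
    # z_{n+1} = (A - B) z_n + B (r_n + xi_plan_n): linear recurrence
    s <- stats::filter(B_eff * (r + xi_plan), params$A - B_eff,
                       method = "recursive", init = z0)
    z <- c(z0, s[-nb])
    z_carry <- s[nb]
    e_plan <- r - z + xi_plan
    plan_err[rows] <- e_plan
    err[rows] <- (1 - g) * e_plan + xi_exec
  }

  out <- data.frame(
    subject_id = subject_id, task = task, condition = condition,
    period = trials$period, block_label = trials$block_label,
    block_type = trials$block_type, trial_in_block = trials$trial_in_block,
    rotation_deg = trials$rotation_deg,
    angular_error_deg = wrap_angle(err),
    points_awarded = NA_integer_,
    is_outlier_removed = FALSE, is_hampel_replaced = FALSE,
    planned_error_deg = wrap_angle(plan_err),
    stringsAsFactors = FALSE
  )
  out$points_awarded <- points_for_trials(out$angular_error_deg, out$period,
                                          condition)
  out
}

# Performance-dependent payoff: 0-10 points scored per trial from the error
# magnitude (10 at 0 deg, 0 at >= 30 deg, linear in between). Reward subjects
# gain the scored points; punishment subjects start from a 4000-point
# endowment and lose the unscored remainder (0-10 lost per trial). Feedback
# is given during the learning period only.
points_for_trials <- function(error_deg, period, condition) {
  pts <- rep(NA_integer_, length(error_deg))
  if (condition == "neutral") return(pts)
  in_learning <- period == "learning"
  scored <- as.integer(round(10 * pmax(0, 1 - abs(error_deg[in_learning]) / 30)))
  pts[in_learning] <- if (condition == "reward") scored else -(10L - scored)
  pts
}

#' Punishment-condition starting endowment, in points
#'
#' Punishment subjects begin with this endowment and lose 0-10 points per
#' trial; their running total is the endowment plus the cumulative sum of
#' (negative) `points_awarded`.
#' @export
PUNISHMENT_ENDOWMENT <- 4000L

#' Simulate a multi-subject, two-task cohort
#'
#' Draws subject-level learner parameters from a [cohort_config()] and
#' simulates every subject through the schedule in both tasks. Parameters
#' `A`, `sigma_plan`, `sigma_exec` and `savings_gain` are drawn once per
#' subject and shared across tasks. The learning rate is drawn per task: in
#' curling jointly with `sigma_plan` at correlation `rho_plan_B` (via a
#' bivariate normal), in reaching independently. The online-correction gain
#' applies in reaching only and is elevated by `delta_g_reinforced` for
#' reward and punishment subjects.
#'
#' @param config a [cohort_config()] object.
#' @param schedule a [make_schedule()] object.
#' @param seed integer seed; defaults to `config$seed`. Identical config and
#'   seed give bit-identical trial tables.
#' @return a trial table (see [simulate_learner()]) for all subjects, tasks
#'   and conditions, with an attribute `"subject_params"`: a data.frame of
#'   the drawn subject-level parameters.
#' @examples
#' cfg <- cohort_config(n_per_condition = 2)
#' tab <- simulate_cohort(cfg, make_schedule(), seed = 7)
#' table(tab$condition, tab$task) / 560
#' @export
simulate_cohort <- function(config, schedule = make_schedule(),
                            seed = config$seed) {
  if (!inherits(config, "cohort_config")) stopf("config must be a cohort_config")
  if (!inherits(schedule, "vmr_schedule")) stopf("schedule must be a vmr_schedule")
  set.seed(seed)

  conds <- rep(config$conditions, each = config$n_per_condition)
  n_subj <- length(conds)
  ids <- sprintf("S%03d", seq_len(n_subj))

  # Correlated standard-normal draws: u_plan drives sigma_plan, and the
  # curling learning rate shares rho_plan_B of it.
  u_plan <- rnorm(n_subj)
  u_curl <- config$rho_plan_B * u_plan +
    sqrt(1 - config$rho_plan_B^2) * rnorm(n_subj)

  sp <- data.frame(
    subject_id = ids, condition = conds,
    A = clamp(rnorm(n_subj, config$A_mean, config$A_sd), 0.5, 0.999),
    sigma_plan = pmax(0, config$sigma_plan_mean + config$sigma_plan_sd * u_plan),
    sigma_exec = pmax(0, rnorm(n_subj, config$sigma_exec_mean, config$sigma_exec_sd)),
    savings_gain = pmax(1, rnorm(n_subj, config$savings_gain_mean, config$savings_gain_sd)),
    stringsAsFactors = FALSE
  )
  sp$B_curling <- clamp(config$B_mean[["curling"]] + config$B_sd * u_curl,
                        0.01, 0.99)
  sp$B_reaching <- clamp(rnorm(n_subj, config$B_mean[["reaching"]], config$B_sd),
                         0.01, 0.99)
  g <- rnorm(n_subj, config$g_mean, config$g_sd) +
    ifelse(conds %in% c("reward", "punishment"), config$delta_g_reinforced, 0)
  sp$g_reaching <- clamp(g, 0, 0.95)

  pieces <- vector("list", n_subj * length(config$tasks))
  k <- 0L
  for (i in seq_len(n_subj)) {
    for (task in config$tasks) {
      B <- if (task == "curling") sp$B_curling[i] else sp$B_reaching[i]
      gv <- if (task == "curling") 0 else sp$g_reaching[i]
      p <- learner_params(A = sp$A[i], B = B, sigma_plan = sp$sigma_plan[i],
                          sigma_exec = sp$sigma_exec[i], g = gv,
                          savings_gain = sp$savings_gain[i])
      k <- k + 1L
      pieces[[k]] <- simulate_learner(p, schedule, task = task,
                                      subject_id = ids[i],
                                      condition = conds[i])
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "subject_params") <- sp
  out
}
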