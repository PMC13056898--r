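#' Parameters of a single simulated learner
#'
#' Bundles the generative parameters for one subject performing one task.
#' The state-space core is governed by the retention factor `A` and the
#' learning rate `B`; behaviour is corrupted by planning noise (injected
#' before the movement plan is executed and therefore visible to the
#' between-trial update) and execution noise (downstream, uninformative).
#' Online correction is a single multiplicative gain `g` on the planned
#' error, only available in the reaching task. `savings_gain` multiplies the
#' effective learning rate on each successive adaptation block to produce
#' faster relearning (savings).
#'
#' @param A retention/decay factor in `[0, 1]`; fraction of the learned state
#'   carried from one trial to the next.
#' @param B learning rate in `[0, 1]`; fraction of the planned error
#'   corrected in the next trial's state update.
#' @param sigma_plan planning-noise SD in degrees (>= 0).
#' @param sigma_exec execution-noise SD in degrees (>= 0).
#' @param g online-correction gain in `[0, 1)`; forced to 0 for curling.
#' @param savings_gain multiplicative increase of the effective learning rate
#'   per successive adaptation block (>= 1); effective rate is capped at 1.
#' @return an object of class `learner_params`.
#' @examples
#' learner_params(A = 0.95, B = 0.2, sigma_plan = 0, sigma_exec = 0)
#' @export
learner_params <- function(A = 0.95, B = 0.15, sigma_plan = 3, sigma_exec = 2,
                           g = 0, savings_gain = 1.15) {
  for (nm in c("A", "B", "sigma_plan", "sigma_exec", "g", "savings_gain")) {
    if (!is_number(get(nm))) stopf("%s must be a single finite number", nm)
  }
  if (A < 0 || A > 1) stopf("A must be in [0, 1]")
  if (B < 0 || B > 1) stopf("B must be in [0, 1]")
  if (sigma_plan < 0 || sigma_exec < 0) stopf("noise SDs must be >= 0")
  if (g < 0 || g >= 1) stopf("g must be in [0, 1)")
  if (savings_gain < 1) stopf("savings_gain must be >= 1")
  structure(list(A = A, B = B, sigma_plan = sigma_plan,
                 sigma_exec = sigma_exec, g = g, savings_gain = savings_gain),
            class = "learner_params")
}

#' @export
print.learner_params <- function(x, ...) {
  cat(sprintf(
    "Learner: A = %.3f, B = %.3f, sigma_plan = %.2f, sigma_exec = %.2f, g = %.2f, savings_gain = %.2f\n",
    x$A, x$B, x$sigma_plan, x$sigma_exec, x$g, x$savings_gain))
  invisible(x)
}

#' Configuration of a synthetic cohort
#'
#' Describes the population from which subject-level learner parameters are
#' drawn. Each subject performs both tasks with shared `A`, planning and
#' execution noise and savings gain. The learning rate is drawn per task
#' around task-specific population means; in curling it is drawn jointly
#' with the planning-noise SD at correlation `rho_plan_B`, encoding the
#' hypothesis that planning noise is informative for between-trial learning.
#' In reaching the learning rate is drawn independently of planning noise
#' (online correction dampens its informational value). The
#' online-correction gain applies in reaching only, elevated by
#' `delta_g_reinforced` for reward and punishment subjects (equally, since
#' reward and punishment did not differ).
#'
#' @param n_per_condition subjects per reinforcement condition (default 22).
#' @param conditions reinforcement conditions simulated.
#' @param tasks tasks simulated.
#' @param A_mean,A_sd population mean/SD of the retention factor.
#' @param B_mean named numeric, population mean of the learning rate per task.
#' @param B_sd population SD of the learning rate.
#' @param sigma_plan_mean,sigma_plan_sd population mean/SD of the
#'   planning-noise SD, degrees.
#' @param sigma_exec_mean,sigma_exec_sd population mean/SD of the
#'   execution-noise SD, degrees.
#' @param g_mean,g_sd population mean/SD of the online-correction gain
#'   (reaching only).
#' @param delta_g_reinforced additive increase of the gain for reward and
#'   punishment subjects in reaching.
#' @param savings_gain_mean,savings_gain_sd population mean/SD of the
#'   per-block savings gain.
#' @param rho_plan_B subject-level correlation between planning-noise SD and
#'   curling learning rate, in `[-1, 1]`.
#' @param seed default seed used by [simulate_cohort()].
#' @return an object of class `cohort_config` (a named list).
#' @examples
#' cfg <- cohort_config(n_per_condition = 2)
#' cfg$rho_plan_B
#' @export
cohort_config <- function(n_per_condition = 22,
                          conditions = c("neutral", "reward", "punishment"),
                          tasks = c("reaching", "curling"),
                          A_mean = 0.95, A_sd = 0.02,
                          B_mean = c(reaching = 0.25, curling = 0.15),
                          B_sd = 0.05,
                          sigma_plan_mean = 3, sigma_plan_sd = 1.2,
                          sigma_exec_mean = 2, sigma_exec_sd = 0.5,
                          g_mean = 0.35, g_sd = 0.08,
                          delta_g_reinforced = 0.2,
                          savings_gain_mean = 1.15, savings_gain_sd = 0.05,
                          rho_plan_B = 0.6,
                          seed = 1L) {
  if (!is_number(n_per_condition) || n_per_condition < 1) {
    stopf("n_per_condition must be >= 1")
  }
  known_cond <- c("neutral", "reward", "punishment")
  bad <- setdiff(conditions, known_cond)
  if (length(bad) || !length(conditions) || anyDuplicated(conditions)) {
    stopf("conditions must be a non-duplicated subset of: %s",
          paste(known_cond, collapse = ", "))
  }
  bad_t <- setdiff(tasks, c("reaching", "curling"))
  if (length(bad_t) || !length(tasks)) {
    stopf("tasks must be a subset of: reaching, curling")
  }
  if (!is_number(rho_plan_B) || rho_plan_B < -1 || rho_plan_B > 1) {
    stopf("rho_plan_B must be in [-1, 1]")
  }
  if (is.null(names(B_mean)) || !all(tasks %in% names(B_mean))) {
    stopf("B_mean must be a named vector with an entry per task")
  }
  structure(list(
    n_per_condition = as.integer(n_per_condition),
    conditions = conditions, tasks = tasks,
    A_mean = A_mean, A_sd = A_sd,
    B_mean = B_mean, B_sd = B_sd,
    sigma_plan_mean = sigma_plan_mean, sigma_plan_sd = sigma_plan_sd,
    sigma_exec_mean = sigma_exec_mean, sigma_exec_sd = sigma_exec_sd,
    g_mean = g_mean, g_sd = g_sd,
    delta_g_reinforced = delta_g_reinforced,
    savings_gain_mean = savings_gain_mean, savings_gain_sd = savings_gain_sd,
    rho_plan_B = rho_plan_B,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  subjects:", x$n_per_condition, "per condition x",
      length(x$conditions), "conditions, tasks:",
      paste(x$tasks, collapse = ", "), "\n")
  cat(sprintf("  A ~ N(%.3f, %.3f); B ~ N(task mean, %.3f); rho(sigma_plan, B_curling) = %.2f\n",
              x$A_mean, x$A_sd, x$B_sd, x$rho_plan_B))
  cat(sprintf("  g(reaching) ~ N(%.2f, %.2f) + %.2f if reinforced\n",
              x$g_mean, x$g_sd, x$delta_g_reinforced))
  invisible(x)
}
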