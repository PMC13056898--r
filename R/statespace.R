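#' Forward predictions of the single-rate state-space model
#'
#' The learner's internal state \eqn{z_n} estimates the applied rotation and
#' evolves as \eqn{z_{n+1} = A z_n + B (r_n - z_n)}: the retention factor
#' `A` describes how much of the estimate is carried (forgotten) from trial
#' to trial and the learning rate `B` how much of the current error
#' \eqn{r_n - z_n} is corrected. The angular hand direction relative to the
#' target is \eqn{y_n = -z_n} and the predicted error is
#' \eqn{e_n = r_n - z_n}.
#'
#' @param A retention factor, in `[0, 1]`.
#' @param B learning rate, in `[0, 1]`.
#' @param r per-trial rotation series.
#' @param z0 initial state (default 0, e.g. at an adaptation-block start).
#' @return list with components `z` (internal states), `y` (hand direction,
#'   `-z`) and `error` (predicted errors `r - z`), each of `length(r)`.
#' @examples
#' predict_series(A = 1, B = 0.5, r = rep(40, 5))$z
#' @export
predict_series <- function(A, B, r, z0 = 0) {
  if (!is_number(A) || A < 0 || A > 1) stopf("A must be in [0, 1]")
  if (!is_number(B) || B < 0 || B > 1) stopf("B must be in [0, 1]")
  if (!is.numeric(r) || any(!is.finite(r))) stopf("r must be finite numeric")
  n <- length(r)
  z <- numeric(n)
  z[1] <- z0
  a <- A - B
  for (i in seq_len(n - 1L)) z[i + 1L] <- a * z[i] + B * r[i]
  list(z = z, y = -z, error = r - z)
}

# fast unchecked SSE of observed errors vs model-predicted errors
ss_objective <- function(par, y, r, z0) {
  a <- par[1] - par[2]
  B <- par[2]
  z <- z0
  sse <- 0
  for (i in seq_along(y)) {
    res <- y[i] - (r[i] - z)
    sse <- sse + res * res
    z <- a * z + B * r[i]
  }
  sse
}

#' Asymptote of the state-space recurrence under constant rotation
#'
#' Under a constant rotation `r` the state converges (for
#' \eqn{1 - A + B > 0}) to \eqn{z^* = B r / (1 - A + B)} and the error to
#' \eqn{e^* = r (1 - A) / (1 - A + B)}; complete learning (`A = 1`) drives
#' the error to zero.
#'
#' @inheritParams predict_series
#' @param r constant rotation, degrees.
#' @return list with `z_star` and `e_star`.
#' @examples
#' fixed_point(0.9, 0.1, 40)
#' @export
fixed_point <- function(A, B, r) {
  if (!is_number(A) || !is_number(B) || !is_number(r)) {
    stopf("A, B, r must be single finite numbers")
  }
  if (1 - A + B <= 0) stopf("fixed point requires 1 - A + B > 0")
  z_star <- B * r / (1 - A + B)
  list(z_star = z_star, e_star = r - z_star)
}

#' Goodness of fit between observed and predicted series
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2).
#' @return list with `r_squared` (`1 - SSE/SST`, SST about the observed
#'   mean), `rmse` (`sqrt(SSE/n)`) and `r_obs_pred` (Pearson correlation;
#'   `NA` when either series has zero variance).
#' @examples
#' goodness_of_fit(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' @export
goodness_of_fit <- function(observed, predicted) {
  n <- length(observed)
  if (n < 2L || length(predicted) != n) {
    stopf("observed and predicted must have equal length >= 2")
  }
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  r <- if (sd(observed) > 0 && sd(predicted) > 0) {
    cor(observed, predicted)
  } else {
    NA_real_
  }
  list(r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
       rmse = sqrt(sse / n),
       r_obs_pred = r)
}

#' Fit the single-rate state-space model to an error series
#'
#' Estimates the retention factor `A` and learning rate `B` by bounded least
#' squares: the observed per-trial errors `y` are matched against the model
#' prediction \eqn{r_n - z_n} with \eqn{z_{n+1} = A z_n + B (r_n - z_n)}
#' and \eqn{z_1 = z0}. Optimisation uses `optim(method = "L-BFGS-B")` with
#' box constraints `[0, 1]` on both parameters from each of several starting
#' points, keeping the best solution; boundary solutions are reported, not
#' treated as errors.
#'
#' The series may be on raw degrees or on the standardised decimal-log scale
#' of [standardise_to_baseline()] (with `r` transformed consistently);
#' `scale` is recorded on the fit for bookkeeping only.
#'
#' @param y observed per-trial error series (removed trials excluded, the
#'   gaps closed by concatenation); length >= 4.
#' @param r per-trial rotation series, same length as `y` (recycled if a
#'   single value is given).
#' @param scale `"raw_degrees"` or `"standardised"`; metadata only.
#' @param starts list of `c(A, B)` starting points for the optimiser.
#' @param z0 initial state.
#' @param tol convergence tolerance on the objective.
#' @return an object of class `statespace_fit` with components `A_hat`,
#'   `B_hat`, `sse`, `r_squared`, `rmse`, `r_obs_pred`, `converged`,
#'   `n_starts_used`, `degenerate` (observed series has zero variance, `B`
#'   unidentifiable), `fitted`, `y`, `r`, `z0`, `scale`. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`,
#'   `plot()` and `simulate()`.
#' @examples
#' r <- rep(40, 40)
#' y <- predict_series(0.95, 0.2, r)$error
#' fit <- fit_statespace(y, r)
#' coef(fit)
#' @export
fit_statespace <- function(y, r, scale = c("raw_degrees", "standardised"),
                           starts = list(c(0.9, 0.1), c(0.99, 0.3), c(0.5, 0.5)),
                           z0 = 0, tol = 1e-9) {
  scale <- match.arg(scale)
  if (!is.numeric(y) || any(!is.finite(y))) stopf("y must be finite numeric")
  if (length(y) < 4L) stopf("insufficient data: need at least 4 trials")
  if (length(r) == 1L) r <- rep(r, length(y))
  if (length(r) != length(y)) stopf("y and r must have equal length")
  degenerate <- sd(y) == 0

  runs <- lapply(starts, function(s) {
    optim(clamp(s, 0, 1), ss_objective, y = y, r = r, z0 = z0,
          method = "L-BFGS-B", lower = c(0, 0), upper = c(1, 1),
          control = list(factr = tol / .Machine$double.eps))
  })
  n_used <- length(runs)
  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(values)]]
  # the fit counts as converged when any start that reached the best
  # objective (within tolerance) reported optimiser success
  at_best <- values <= best$value + 1e-6 * max(1, abs(best$value))
  codes <- vapply(runs, `[[`, numeric(1), "convergence")
  # an essentially-exact fit counts as success even when the line search
  # reports abnormal termination at the bottom of the objective
  converged <- any(codes[at_best] == 0) ||
    best$value <= 1e-8 * max(1, sum(y^2))

  pred <- predict_series(best$par[1], best$par[2], r, z0)$error
  gof <- goodness_of_fit(y, pred)
  structure(list(
    A_hat = best$par[1], B_hat = best$par[2],
    sse = best$value,
    r_squared = gof$r_squared, rmse = gof$rmse, r_obs_pred = gof$r_obs_pred,
    converged = converged,
    n_starts_used = n_used,
    degenerate = degenerate,
    fitted = pred, y = y, r = r, z0 = z0, scale = scale,
    call = match.call()
  ), class = "statespace_fit")
}

#' @export
print.statespace_fit <- function(x, digits = 4, ...) {
  cat("Single-rate state-space model fit (", x$scale, ", ",
      length(x$y), " trials)\n", sep = "")
  cat(sprintf("  A = %.*f, B = %.*f\n", digits, x$A_hat, digits, x$B_hat))
  cat(sprintf("  R^2 = %.*f, RMSE = %.*g, r(obs, pred) = %.*f\n",
              digits, x$r_squared, digits, x$rmse, digits, x$r_obs_pred))
  if (!x$converged) cat("  warning: optimiser did not report convergence\n")
  if (x$degenerate) cat("  warning: degenerate series (zero variance); B unidentifiable\n")
  invisible(x)
}

#' @export
coef.statespace_fit <- function(object, ...) {
  c(A = object$A_hat, B = object$B_hat)
}

#' @export
fitted.statespace_fit <- function(object, ...) object$fitted

#' @export
residuals.statespace_fit <- function(object, ...) object$y - object$fitted

#' @rdname fit_statespace
#' @param object,x a `statespace_fit`.
#' @param ... further arguments (ignored).
#' @export
summary.statespace_fit <- function(object, ...) {
  structure(list(fit = object,
                 n = length(object$y),
                 resid_summary = summary(residuals(object))),
            class = "summary.statespace_fit")
}

#' @export
print.summary.statespace_fit <- function(x, ...) {
  print(x$fit)
  cat("Residuals:\n")
  print(x$resid_summary)
  invisible(x)
}

#' Predicted error series from a fitted state-space model
#'
#' With no new data, returns the fitted values; with a new rotation series
#' `r`, forward-simulates the fitted parameters through it.
#'
#' @param object a `statespace_fit`.
#' @param r optional new rotation series.
#' @param z0 initial state for the new series.
#' @param ... ignored.
#' @return numeric vector of predicted errors.
#' @export
predict.statespace_fit <- function(object, r = NULL, z0 = object$z0, ...) {
  if (is.null(r)) return(object$fitted)
  predict_series(object$A_hat, object$B_hat, r, z0)$error
}

#' Simulate error series from a fitted state-space model
#'
#' Draws `nsim` series of the fitted deterministic prediction plus Gaussian
#' residual noise with the residual standard deviation of the fit.
#'
#' @param object a `statespace_fit`.
#' @param nsim number of series.
#' @param seed optional seed.
#' @param ... ignored.
#' @return a data.frame with `nsim` columns, `length(y)` rows.
#' @export
simulate.statespace_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$y)
  sig <- sqrt(object$sse / max(n - 2L, 1L))
  out <- as.data.frame(replicate(nsim, object$fitted + rnorm(n, 0, sig)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.statespace_fit <- function(x, ...) {
  n <- length(x$y)
  plot(seq_len(n), x$y, pch = 16, col = "grey40",
       xlab = "Trial", ylab = paste0("Angular error (", x$scale, ")"),
       main = sprintf("State-space fit: A = %.3f, B = %.3f", x$A_hat, x$B_hat),
       ...)
  lines(seq_len(n), x$fitted, col = "firebrick", lwd = 2)
  legend("topright", bty = "n", legend = c("observed", "model"),
         col = c("grey40", "firebrick"), pch = c(16, NA), lty = c(NA, 1),
         lwd = c(NA, 2))
  invisible(x)
}

#' Fit the state-space model block-wise across a cohort
#'
#' For every subject/task/adaptation-block series in a preprocessed trial
#' table, drops removed trials (concatenating the gaps), optionally
#' log-standardises the errors to the subject's baseline median (with the
#' rotation transformed consistently) and fits [fit_statespace()] from
#' `z0 = 0`.
#'
#' @param table a preprocessed trial table (see [preprocess_trials()]).
#' @param scale `"standardised"` (decimal-log errors relative to baseline;
#'   the default used for cohort analyses) or `"raw_degrees"`.
#' @param eps floor for the log transform, degrees.
#' @param ... passed to [fit_statespace()].
#' @return data.frame of per-block fit records: `subject_id`, `task`,
#'   `block_label`, `A_hat`, `B_hat`, `r_squared`, `rmse`, `r_obs_pred`,
#'   `converged`.
#' @examples
#' tab <- simulate_learner(learner_params(), make_schedule(), "curling", seed = 2)
#' fits <- fit_blocks(preprocess_trials(tab)$table)
#' head(fits)
#' @export
fit_blocks <- function(table, scale = c("standardised", "raw_degrees"),
                       eps = 0.5, ...) {
  scale <- match.arg(scale)
  check_trial_table(table)
  if (scale == "standardised") {
    ad <- standardise_to_baseline(table, eps = eps)
    ad$fit_y <- ad$std_error
    ad$fit_r <- ad$std_rotation
  } else {
    ad <- table[table$block_type == "adaptation" & !table$is_outlier_removed, ]
    ad$fit_y <- ad$angular_error_deg
    ad$fit_r <- ad$rotation_deg
  }
  key <- paste(ad$subject_id, ad$task, ad$block_label, sep = "\r")
  groups <- split(seq_len(nrow(ad)), key)
  recs <- lapply(groups, function(rows) {
    rows <- rows[order(ad$trial_in_block[rows])]
    fit <- fit_statespace(ad$fit_y[rows], ad$fit_r[rows], scale = scale, ...)
    data.frame(
      subject_id = ad$subject_id[rows[1]], task = ad$task[rows[1]],
      block_label = ad$block_label[rows[1]],
      A_hat = fit$A_hat, B_hat = fit$B_hat, r_squared = fit$r_squared,
      rmse = fit$rmse, r_obs_pred = fit$r_obs_pred, converged = fit$converged,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$subject_id, out$task, out$block_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
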