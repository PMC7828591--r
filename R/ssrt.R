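## SSRT estimation and race-model screening.
## All estimators operate on test trials only (block > 0).

round_half_up <- function(x) floor(x + 0.5)

#' Behavioral summary of a stop-signal session
#'
#' Computes the standard SST descriptives over test trials: go omission and
#' choice-error probabilities, mean and SD of responded go RTs, the nth RT
#' of the omission-augmented go-RT distribution, the probability of
#' responding on a stop trial, the mean SSD over all stop trials, and the
#' mean signal-respond RT (responded stop trials).
#'
#' The augmented go-RT distribution contains every responded go RT
#' (choice errors and premature responses included) plus one copy of the
#' subject's maximum RT per go omission; `nth_rt` is its n-th smallest
#' value with `n = round(N * p(respond|stop))` (half away from zero,
#' clamped to `[1, N]`).
#'
#' @param log A `trial_log` with at least one go and one stop test trial.
#' @return An object of class `sst_summary`: a list with elements
#'   `p_go_omission`, `p_choice_error`, `mean_go_rt`, `sd_go_rt`, `nth_rt`,
#'   `p_respond_stop`, `mean_ssd`, `mean_signal_respond_rt`, `n_go`,
#'   `n_stop`, `n_index`.
#' @export
summarize_behavior <- function(log) {
  tl <- test_trials(log)
  go <- tl[tl$type == "go", , drop = FALSE]
  st <- tl[tl$type == "stop", , drop = FALSE]
  if (nrow(go) < 1L)
    stop("insufficient trials: no go test trials in log")
  if (nrow(st) < 1L)
    stop("insufficient trials: no stop test trials in log")

  go_rts <- go$rt_ms[go$responded]
  if (length(go_rts) < 1L)
    stop("insufficient trials: no responded go trials")
  n_omit <- sum(!go$responded)
  aug <- sort(c(go_rts, rep(max(go_rts), n_omit)))
  p_respond_stop <- mean(st$responded)
  n_index <- min(max(round_half_up(length(aug) * p_respond_stop), 1L),
                 length(aug))
  sr_rts <- st$rt_ms[st$responded]

  structure(list(
    p_go_omission = n_omit / nrow(go),
    p_choice_error = mean(!go$correct[go$responded]),
    mean_go_rt = mean(go_rts),
    sd_go_rt = if (length(go_rts) > 1L) sd(go_rts) else NA_real_,
    nth_rt = aug[n_index],
    p_respond_stop = p_respond_stop,
    mean_ssd = mean(st$ssd_ms),
    mean_signal_respond_rt = if (length(sr_rts)) mean(sr_rts) else NA_real_,
    n_go = nrow(go), n_stop = nrow(st), n_index = n_index
  ), class = "sst_summary")
}

#' @export
print.sst_summary <- function(x, digits = 4, ...) {
  cat("Stop-signal behavioral summary (", x$n_go, " go, ", x$n_stop,
      " stop test trials)\n", sep = "")
  v <- unlist(x[c("p_go_omission", "p_choice_error", "mean_go_rt",
                  "sd_go_rt", "nth_rt", "p_respond_stop", "mean_ssd",
                  "mean_signal_respond_rt")])
  print(round(v, digits), ...)
  invisible(x)
}

#' Screen a session against the horse-race model's assumptions
#'
#' A session is flagged invalid when the probability of responding on a
#' stop trial falls outside `[p_low, p_high]` (default 0.25-0.75) or when
#' the mean signal-respond RT is not strictly below the mean go RT; both
#' are the standard screening rules under which SSRT estimation is
#' considered unreliable and is skipped.  If no stop trial carries a
#' response, the signal-respond comparison is indeterminate and the
#' session is invalid.
#'
#' @param log A `trial_log`.
#' @param p_low,p_high Admissible bounds on p(respond|stop).
#' @return An object of class `race_validity`: list with `p_respond_stop`,
#'   `signal_respond_vs_go_ok` (`NA` when indeterminate), `p_in_bounds`,
#'   `valid`, and a character vector `reasons`.
#' @export
check_race_assumptions <- function(log, p_low = 0.25, p_high = 0.75) {
  s <- summarize_behavior(log)
  reasons <- character(0)
  p_ok <- s$p_respond_stop >= p_low && s$p_respond_stop <= p_high
  if (!p_ok)
    reasons <- c(reasons, sprintf(
      "p(respond|stop) = %.3f out of bounds [%.2f, %.2f]",
      s$p_respond_stop, p_low, p_high))
  if (is.na(s$mean_signal_respond_rt)) {
    sr_ok <- NA
    reasons <- c(reasons,
                 "no responded stop trials: signal-respond RT check indeterminate")
  } else {
    sr_ok <- s$mean_signal_respond_rt < s$mean_go_rt
    if (!sr_ok)
      reasons <- c(reasons, sprintf(
        "mean signal-respond RT (%.1f ms) not below mean go RT (%.1f ms)",
        s$mean_signal_respond_rt, s$mean_go_rt))
  }
  structure(list(
    p_respond_stop = s$p_respond_stop,
    signal_respond_vs_go_ok = sr_ok,
    p_in_bounds = p_ok,
    valid = p_ok && isTRUE(sr_ok),
    reasons = reasons
  ), class = "race_validity")
}

#' @export
print.race_validity <- function(x, ...) {
  cat("Race-model validity:", if (x$valid) "VALID" else "INVALID", "\n")
  cat("  p(respond|stop) =", format(x$p_respond_stop, digits = 3), "\n")
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Estimate the stop-signal reaction time
#'
#' Integration method (default): the finishing time of the stop process is
#' the nth RT of the omission-augmented go-RT distribution, where
#' `n = round(N * p(respond|stop))`; `SSRT = nth RT - mean SSD` with the
#' mean SSD taken over all stop test trials.  Go omissions are replaced by
#' the subject's maximum RT and every responded go trial is included
#' (choice errors and premature responses too).  Mean method:
#' `SSRT = mean go RT - mean SSD`.
#'
#' Estimation refuses to run on a session failing
#' [check_race_assumptions()] unless `override_validity = TRUE`.
#'
#' @param log A `trial_log`.
#' @param method `"integration"` or `"mean"`.
#' @param override_validity Estimate even when the race-model screening
#'   fails (for methodological studies); default `FALSE`.
#' @param p_low,p_high Passed to [check_race_assumptions()].
#' @return An object of class `ssrt_estimate`: list with `method`, `ssrt`,
#'   `finish_time` (nth RT or mean go RT), `mean_ssd`, `n_index`
#'   (integration only), `p_respond_stop`, and the `validity` report.
#' @examples
#' log <- simulate_session(race_params(p_go_omission = 0), seed = 2)
#' estimate_ssrt(log)
#' @export
estimate_ssrt <- function(log, method = c("integration", "mean"),
                          override_validity = FALSE,
                          p_low = 0.25, p_high = 0.75) {
  method <- match.arg(method)
  validity <- check_race_assumptions(log, p_low, p_high)
  if (!validity$valid && !override_validity) {
    msg <- paste0("race-model assumptions violated; SSRT not estimated:\n  ",
                  paste(validity$reasons, collapse = "\n  "))
    cond <- structure(class = c("stopnet_validity_error", "error", "condition"),
                      list(message = msg, call = sys.call(),
                           validity = validity))
    stop(cond)
  }
  s <- summarize_behavior(log)
  if (method == "integration") {
    finish <- s$nth_rt
    n_index <- s$n_index
  } else {
    finish <- s$mean_go_rt
    n_index <- NA_integer_
  }
  structure(list(
    method = method,
    ssrt = finish - s$mean_ssd,
    finish_time = finish,
    mean_ssd = s$mean_ssd,
    n_index = n_index,
    p_respond_stop = s$p_respond_stop,
    validity = validity
  ), class = "ssrt_estimate")
}

#' @export
print.ssrt_estimate <- function(x, ...) {
  cat(sprintf("SSRT (%s method): %.2f ms\n", x$method, x$ssrt))
  cat(sprintf("  finishing-time estimate %.2f ms - mean SSD %.2f ms\n",
              x$finish_time, x$mean_ssd))
  if (!is.na(x$n_index))
    cat(sprintf("  n index = %d, p(respond|stop) = %.3f\n",
                x$n_index, x$p_respond_stop))
  invisible(x)
}

#' @export
coef.ssrt_estimate <- function(object, ...) c(ssrt = object$ssrt)
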