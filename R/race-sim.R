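#' Stop-signal task configuration
#'
#' Describes the trial structure of a stop-signal session: block layout,
#' proportion of stop trials, staircase settings for the stop-signal delay
#' (SSD), and the response-registration deadline on go trials.  The defaults
#' reproduce a typical adolescent SST protocol: one practice block of 40
#' trials followed by three test blocks of 80 trials each, 30% stop trials,
#' and an initial SSD of 500 ms adjusted in 50-ms steps.  The default
#' registration deadline is 2000 ms: in such protocols the go stimulus is
#' displayed for at most 1000 ms but responses during the following blank
#' are still recorded, and observed RT distributions extend beyond 1000 ms
#' while omission rates stay near half a percent.
#'
#' @param n_test_blocks Number of test blocks.
#' @param trials_per_block Trials per test block.
#' @param stop_proportion Fraction of trials carrying a stop signal, in
#'   (0, 1).  Each block contains `round(trials_per_block * stop_proportion)`
#'   stop trials at randomized positions.
#' @param ssd_initial Initial stop-signal delay in ms.
#' @param ssd_step Staircase step in ms (> 0): SSD increases by this amount
#'   after a successful stop and decreases after a failed stop.
#' @param go_max_duration Response-registration deadline in ms; go finishes
#'   later than this become omissions.
#' @param iti_range Inter-trial interval range in ms (metadata only; the
#'   race is unaffected).
#' @param practice_trials Number of practice trials (block 0); practice is
#'   simulated but excluded from all estimators.
#' @param carry_ssd_across_blocks If `TRUE` (default) the staircase state is
#'   carried from one block to the next rather than reset to `ssd_initial`.
#' @return An object of class `task_config`.
#' @seealso [simulate_session()]
#' @export
task_config <- function(n_test_blocks = 3, trials_per_block = 80,
                        stop_proportion = 0.3, ssd_initial = 500,
                        ssd_step = 50, go_max_duration = 2000,
                        iti_range = c(1100, 1900), practice_trials = 40,
                        carry_ssd_across_blocks = TRUE) {
  stopifnot(n_test_blocks >= 1, trials_per_block >= 1)
  if (stop_proportion <= 0 || stop_proportion >= 1)
    stop("`stop_proportion` must lie strictly in (0, 1)")
  if (ssd_step <= 0) stop("`ssd_step` must be positive")
  if (ssd_initial < 0) stop("`ssd_initial` must be non-negative")
  if (go_max_duration <= 0) stop("`go_max_duration` must be positive")
  structure(list(
    n_test_blocks = as.integer(n_test_blocks),
    trials_per_block = as.integer(trials_per_block),
    stop_proportion = stop_proportion,
    ssd_initial = ssd_initial,
    ssd_step = ssd_step,
    go_max_duration = go_max_duration,
    iti_range = iti_range,
    practice_trials = as.integer(practice_trials),
    carry_ssd_across_blocks = isTRUE(carry_ssd_across_blocks)
  ), class = "task_config")
}

#' Horse-race model parameters
#'
#' Parameters of the independent horse-race model backing the simulator.
#' Go finishing times follow an ex-Gaussian law (normal with mean `go_mu`
#' and SD `go_sigma` plus an independent exponential with mean `go_tau`, so
#' the distribution mean is `go_mu + go_tau`).  The stop process is either a
#' constant latency (`stop_sigma = stop_tau = 0`) or itself ex-Gaussian.
#' Go omissions and choice errors are injected independently of the race at
#' the configured rates; a trigger failure makes the stop process fail to
#' launch on that trial.
#'
#' The defaults (`go_mu` 480, `go_sigma` 90, `go_tau` 200 ms; constant stop
#' latency 160 ms; omission rate 0.005; choice-error rate 0.05) are
#' calibrated so that large simulated sessions resemble reported adolescent
#' SST summaries (mean go RT near 680 ms, omission probability near 0.005).
#'
#' @param go_mu,go_sigma,go_tau Ex-Gaussian parameters of the go process, ms.
#' @param stop_mu,stop_sigma,stop_tau Stop-latency law, ms; the default is a
#'   constant 160 ms.
#' @param p_go_omission Probability that the go response is omitted.
#' @param p_choice_error Probability that a responded go trial carries the
#'   wrong key (label flip; the RT still counts, as in the integration
#'   method's inclusion rule).
#' @param trigger_failure_rate Probability the stop process is not triggered
#'   on a stop trial (default 0).
#' @return An object of class `race_params`.
#' @export
race_params <- function(go_mu = 480, go_sigma = 90, go_tau = 200,
                        stop_mu = 160, stop_sigma = 0, stop_tau = 0,
                        p_go_omission = 0.005, p_choice_error = 0.05,
                        trigger_failure_rate = 0) {
  if (go_sigma < 0 || go_tau < 0 || stop_sigma < 0 || stop_tau < 0)
    stop("sigma and tau parameters must be non-negative")
  rates <- c(p_go_omission, p_choice_error, trigger_failure_rate)
  if (any(rates < 0 | rates > 1))
    stop("rate parameters must lie in [0, 1]")
  structure(list(
    go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
    stop_mu = stop_mu, stop_sigma = stop_sigma, stop_tau = stop_tau,
    p_go_omission = p_go_omission, p_choice_error = p_choice_error,
    trigger_failure_rate = trigger_failure_rate
  ), class = "race_params")
}

#' Sample from an ex-Gaussian reaction-time law
#'
#' Draws `n` values from the convolution of a normal (`mu`, `sigma`) and an
#' exponential with mean `tau`, the standard descriptive law for response
#' times.  Draws are truncated below at zero.  The distribution mean is
#' `mu + tau` and its SD is `sqrt(sigma^2 + tau^2)`.
#'
#' @param n Number of draws (>= 1).
#' @param mu,sigma,tau Ex-Gaussian parameters in ms; `sigma, tau >= 0`.
#' @return Numeric vector of `n` non-negative values.
#' @examples
#' set.seed(1)
#' mean(sample_ex_gaussian(1e4, 500, 50, 100))  # close to 600
#' @export
sample_ex_gaussian <- function(n, mu, sigma, tau) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("`n` must be at least 1")
  if (sigma < 0 || tau < 0) stop("`sigma` and `tau` must be non-negative")
  x <- rnorm(n, mean = mu, sd = sigma)
  if (tau > 0) x <- x + rexp(n, rate = 1 / tau)
  pmax(x, 0)
}

#' Simulate a stop-signal session under the horse-race model
#'
#' Runs a full SST session: go finishing times race against a stop process
#' launched `SSD` ms after the go stimulus, and a one-up-one-down staircase
#' adjusts the SSD by `ssd_step` toward 50% successful inhibition.  A stop
#' trial is inhibited iff `SSD + stop latency < go finishing time` (strict:
#' ties produce a response) and the stop process was triggered.  Responses
#' later than `go_max_duration` become omissions.  After a successful stop
#' the SSD increases by one step (harder), after a failed stop it decreases
#' (easier); the SSD is clamped to `[0, go_max_duration + 1000]`.
#'
#' The returned log retains the latent finishing times so inhibition
#' outcomes can be re-derived exactly in oracle checks; estimators ignore
#' them.
#'
#' @param params A [race_params()] object.
#' @param task A [task_config()] object.
#' @param seed Optional integer seed; recorded in the log attributes.
#' @return A data frame of class `trial_log` with one row per trial and
#'   columns `block` (0 = practice), `trial`, `type` (`"go"`/`"stop"`),
#'   `ssd_ms` (stop trials only), `responded`, `rt_ms`, `correct`, and the
#'   latent columns `go_finish_ms`, `stop_latency_ms`, `trigger_failure`.
#' @examples
#' log <- simulate_session(race_params(), task_config(), seed = 7)
#' table(test_trials(log)$type)
#' @export
simulate_session <- function(params = race_params(), task = task_config(),
                             seed = NULL) {
  stopifnot(inherits(params, "race_params"), inherits(task, "task_config"))
  if (!is.null(seed)) set.seed(seed)

  blocks <- integer(0)
  if (task$practice_trials > 0)
    blocks <- rep(0L, task$practice_trials)
  blocks <- c(blocks,
              rep(seq_len(task$n_test_blocks), each = task$trials_per_block))
  n <- length(blocks)

  ## stop-trial placement: fixed count per block, random positions
  is_stop <- logical(n)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    n_stop <- round(length(idx) * task$stop_proportion)
    is_stop[sample(idx, n_stop)] <- TRUE
  }

  go_finish <- sample_ex_gaussian(n, params$go_mu, params$go_sigma,
                                  params$go_tau)
  omitted <- runif(n) < params$p_go_omission
  flipped <- runif(n) < params$p_choice_error
  trig_fail <- runif(n) < params$trigger_failure_rate
  stop_lat <- if (params$stop_sigma == 0 && params$stop_tau == 0)
    rep(params$stop_mu, n)
  else
    sample_ex_gaussian(n, params$stop_mu, params$stop_sigma, params$stop_tau)

  ssd <- rep(NA_real_, n)
  responded <- !omitted & go_finish <= task$go_max_duration

  ssd_max <- task$go_max_duration + 1000
  cur <- task$ssd_initial
  prev_block <- NA_integer_
  for (i in which(is_stop)) {
    if (!task$carry_ssd_across_blocks && !is.na(prev_block) &&
        blocks[i] != prev_block)
      cur <- task$ssd_initial
    prev_block <- blocks[i]
    ssd[i] <- cur
    inhibited <- !trig_fail[i] && (cur + stop_lat[i] < go_finish[i])
    responded[i] <- !inhibited && !omitted[i] &&
      go_finish[i] <= task$go_max_duration
    cur <- cur + if (responded[i]) -task$ssd_step else task$ssd_step
    cur <- min(max(cur, 0), ssd_max)
  }

  rt <- ifelse(responded, go_finish, NA_real_)
  correct <- ifelse(is_stop, !responded,
                    ifelse(responded, !flipped, NA))

  log <- data.frame(
    block = blocks,
    trial = seq_len(n),
    type = ifelse(is_stop, "stop", "go"),
    ssd_ms = ssd,
    responded = responded,
    rt_ms = rt,
    correct = correct,
    go_finish_ms = go_finish,
    stop_latency_ms = ifelse(is_stop, stop_lat, NA_real_),
    trigger_failure = ifelse(is_stop, trig_fail, NA),
    stringsAsFactors = FALSE
  )
  attr(log, "task") <- task
  attr(log, "params") <- params
  attr(log, "seed") <- seed
  class(log) <- c("trial_log", "data.frame")
  log
}

#' Restrict a trial log to test blocks
#'
#' Drops practice trials (block 0); all behavioral estimators operate on
#' test blocks only.
#'
#' @param log A `trial_log`.
#' @return The test-block subset, same class.
#' @export
test_trials <- function(log) {
  stopifnot(is.data.frame(log), "block" %in% names(log))
  log[log$block > 0L, , drop = FALSE]
}

#' Write / read a trial log as CSV
#'
#' Plain-CSV round trip for trial logs (header row, one row per trial).
#' Latent columns are preserved so oracle checks survive serialization.
#'
#' @param log A `trial_log`.
#' @param path File path.
#' @return `read_trial_log` returns a `trial_log` data frame.
#' @export
write_trial_log <- function(log, path) {
  write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  log <- read.csv(path, stringsAsFactors = FALSE)
  class(log) <- c("trial_log", "data.frame")
  log
}
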