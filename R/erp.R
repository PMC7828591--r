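## Epoched-ERP containers and the stop-minus-slow-go N2 derivation.

#' Epoched ERP data for one subject
#'
#' A lightweight container for baseline-ready single-trial EEG epochs:
#' a trials x channels x samples amplitude array (microvolts), the sampling
#' rate, the epoch window relative to the time-locking event, channel
#' labels, per-trial condition labels, and per-trial go RTs for go trials.
#' Sample timestamps sit at exact multiples of `1000 / sampling_rate` ms
#' from the window start; with inclusive endpoints the array must carry
#' `diff(epoch_window) / 1000 * sampling_rate + 1` samples (251 for a
#' -200..800 ms window at 250 Hz).
#'
#' @param data Numeric array, trials x channels x samples, microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_window Length-2 ms pair relative to the event (e.g.
#'   `c(-200, 800)`).
#' @param channels Character vector of channel labels, one per array row 2.
#' @param condition Per-trial labels from
#'   `{"successful_stop", "unsuccessful_stop", "go"}`.
#' @param rt_ms Per-trial go RT in ms (`NA` on stop trials).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, sampling_rate, epoch_window, channels,
                      condition, rt_ms = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a trials x channels x samples array")
  d <- dim(data)
  expected <- diff(epoch_window) / 1000 * sampling_rate + 1
  if (!isTRUE(all.equal(d[3], expected)))
    stop(sprintf("sample count %d inconsistent with window/rate (expected %g)",
                 d[3], expected))
  if (length(channels) != d[2]) stop("channel labels do not match data")
  if (length(condition) != d[1]) stop("condition labels do not match data")
  bad <- setdiff(unique(condition),
                 c("successful_stop", "unsuccessful_stop", "go"))
  if (length(bad)) stop("unknown condition label(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(rt_ms)) rt_ms <- rep(NA_real_, d[1])
  if (length(rt_ms) != d[1]) stop("rt_ms does not match trial count")
  structure(list(
    data = data, sampling_rate = sampling_rate,
    epoch_window = as.numeric(epoch_window),
    channels = as.character(channels),
    condition = as.character(condition), rt_ms = as.numeric(rt_ms)
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d trials x %d channels x %d samples, %g Hz, %g..%g ms\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate, x$epoch_window[1], x$epoch_window[2]))
  print(table(x$condition))
  invisible(x)
}

#' Sample timestamps of an epoch container or wave
#'
#' @param x An `epoch_set` or `erp_wave`.
#' @return Numeric vector of sample times in ms relative to the event.
#' @export
sample_times <- function(x) {
  seq(x$epoch_window[1], x$epoch_window[2], by = 1000 / x$sampling_rate)
}

subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$sampling_rate,
            epochs$epoch_window, epochs$channels,
            epochs$condition[idx], epochs$rt_ms[idx])
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window (default -200..0 ms, sample-grid endpoints inclusive).
#'
#' @param epochs An `epoch_set`.
#' @param baseline Length-2 ms pair inside the epoch window.
#' @return A baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (baseline[1] < epochs$epoch_window[1] ||
      baseline[2] > epochs$epoch_window[2])
    stop("baseline window lies outside the epoch window")
  t <- sample_times(epochs)
  sel <- t >= baseline[1] & t <= baseline[2]
  if (!any(sel)) stop("baseline window contains no samples")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  out <- epochs
  out$data <- epochs$data - array(bl, dim = dim(epochs$data))
  out
}

#' Median-split go trials into slow and fast
#'
#' Tags each go trial by its RT relative to the subject's median go RT:
#' strictly above the median is `"slow"`, strictly below is `"fast"`, and
#' ties at the median are assigned to `"slow"` (deterministic rule).
#' Under the horse-race model slow go trials are the ones comparable to
#' successful stop trials, so the slow-go average serves as the go-locked
#' activity removed by the difference wave.
#'
#' @param epochs An `epoch_set` with at least 2 go trials carrying RTs.
#' @return Character vector over all trials: `"slow"`/`"fast"` on go
#'   trials, `NA` elsewhere.
#' @export
median_split_go <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  go <- epochs$condition == "go" & !is.na(epochs$rt_ms)
  if (sum(go) < 2L) stop("median split needs at least 2 go trials with RTs")
  med <- median(epochs$rt_ms[go])
  tag <- rep(NA_character_, length(epochs$condition))
  tag[go] <- ifelse(epochs$rt_ms[go] >= med, "slow", "fast")
  tag
}

#' Average epochs into a condition ERP
#'
#' Pointwise trial mean per channel over the selected trials, either by
#' condition label (optionally intersected with a [median_split_go()] tag)
#' or by an explicit trial index.
#'
#' @param epochs An `epoch_set`.
#' @param label Condition label to average (ignored when `trials` given).
#' @param tags Optional per-trial tag vector (from [median_split_go()]).
#' @param tag Tag value to keep, e.g. `"slow"`.
#' @param trials Optional explicit logical/integer trial selection.
#' @return An object of class `erp_wave`: list with `amplitude`
#'   (channels x samples matrix), `sampling_rate`, `epoch_window`,
#'   `channels`, `n_trials`.
#' @export
condition_erp <- function(epochs, label = NULL, tags = NULL, tag = NULL,
                          trials = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(trials)) {
    if (is.null(label)) stop("give either `label` or `trials`")
    trials <- epochs$condition == label
    if (!is.null(tags)) {
      if (is.null(tag)) stop("`tag` required when `tags` is given")
      trials <- trials & !is.na(tags) & tags == tag
    }
  }
  idx <- if (is.logical(trials)) which(trials) else as.integer(trials)
  if (length(idx) < 1L) stop("no trials match the requested condition")
  amp <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
  dimnames(amp) <- list(epochs$channels, NULL)
  structure(list(
    amplitude = amp, sampling_rate = epochs$sampling_rate,
    epoch_window = epochs$epoch_window, channels = epochs$channels,
    n_trials = length(idx)
  ), class = "erp_wave")
}

#' @export
print.erp_wave <- function(x, ...) {
  cat(sprintf("erp_wave: %d channels x %d samples (average of %d trials)\n",
              nrow(x$amplitude), ncol(x$amplitude), x$n_trials))
  invisible(x)
}

#' Pointwise difference of two ERP waves
#'
#' Computes `a - b` (e.g. successful stop minus slow go), requiring
#' matching channels, sampling rate, and epoch window.
#'
#' @param a,b `erp_wave` objects.
#' @return An `erp_wave`; `n_trials` is the minimum of the inputs'.
#' @export
difference_wave <- function(a, b) {
  stopifnot(inherits(a, "erp_wave"), inherits(b, "erp_wave"))
  if (!identical(a$channels, b$channels) ||
      !identical(a$epoch_window, b$epoch_window) ||
      !identical(a$sampling_rate, b$sampling_rate) ||
      !identical(dim(a$amplitude), dim(b$amplitude)))
    stop("waves have mismatching channels, window, or sampling")
  out <- a
  out$amplitude <- a$amplitude - b$amplitude
  out$n_trials <- min(a$n_trials, b$n_trials)
  out
}

#' Region-of-interest specification
#'
#' A channel subset plus a measurement window; the default window 180-250
#' ms brackets the N2 peak of the stop-locked difference wave over right
#' anterior-frontal sites.
#'
#' @param channels Channel labels forming the ROI (default the six
#'   placeholder labels `ROI1..ROI6` used by the synthetic generator; real
#'   montages supply their own labels).
#' @param window Length-2 ms pair, endpoints inclusive on the sample grid.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(channels = paste0("ROI", 1:6), window = c(180, 250)) {
  stopifnot(length(window) == 2L, window[1] <= window[2],
            length(channels) >= 1L)
  structure(list(channels = as.character(channels),
                 window = as.numeric(window)), class = "roi_spec")
}

#' Mean amplitude over an ROI and time window
#'
#' Averages the wave over the ROI channels, then over the samples whose
#' timestamps fall inside `[window[1], window[2]]` (inclusive endpoints on
#' the sample grid; at 250 Hz the default 180-250 ms window contains the 18
#' samples 180, 184, ..., 248 ms).
#'
#' @param wave An `erp_wave`.
#' @param roi A [roi_spec()].
#' @return Scalar mean amplitude in microvolts.
#' @export
roi_mean_amplitude <- function(wave, roi = roi_spec()) {
  stopifnot(inherits(wave, "erp_wave"), inherits(roi, "roi_spec"))
  missing_ch <- setdiff(roi$channels, wave$channels)
  if (length(missing_ch))
    stop("ROI channels absent from wave: ", paste(missing_ch, collapse = ", "))
  if (roi$window[1] < wave$epoch_window[1] ||
      roi$window[2] > wave$epoch_window[2])
    stop("ROI window lies outside the epoch window")
  t <- sample_times(wave)
  sel <- t >= roi$window[1] & t <= roi$window[2]
  if (!any(sel)) stop("ROI window contains no samples")
  ch <- match(roi$channels, wave$channels)
  mean(colMeans(wave$amplitude[ch, sel, drop = FALSE]))
}

#' Derive the N2 measure from one subject's epochs
#'
#' The full derivation: baseline correction, median split of go trials,
#' successful-stop ERP minus slow-go ERP, and the ROI mean amplitude of the
#' difference wave over the N2 window.  Unsuccessful-stop epochs are
#' carried in the container but take no part in the derivation.
#'
#' @param epochs An `epoch_set`.
#' @param roi A [roi_spec()].
#' @param baseline Baseline window, ms pair.
#' @return Scalar N2 mean amplitude in microvolts.
#' @examples
#' ep <- generate_epoch_set(n2_amplitude = -2, noise_sd = 0, seed = 1)
#' derive_n2(ep)
#' @export
derive_n2 <- function(epochs, roi = roi_spec(), baseline = c(-200, 0)) {
  ep <- baseline_correct(epochs, baseline)
  tags <- median_split_go(ep)
  stop_erp <- condition_erp(ep, "successful_stop")
  slow_go <- condition_erp(ep, "go", tags = tags, tag = "slow")
  roi_mean_amplitude(difference_wave(stop_erp, slow_go), roi)
}

#' Spearman-Brown step-up of a half-test correlation
#'
#' @param r Correlation between two test halves.
#' @return `2 * r / (1 + r)`.
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)

#' Split-half reliability of the N2 derivation
#'
#' Splits every subject's trials into odd- and even-numbered halves within
#' each condition, runs the full stop-minus-slow-go N2 derivation on each
#' half, correlates the two half measures across subjects, and applies the
#' Spearman-Brown step-up `2r / (1 + r)`.
#'
#' @param subjects List of `epoch_set`s, one per subject; each needs at
#'   least 4 successful-stop trials and 8 go trials (so each half retains a
#'   median split with >= 2 slow-go trials).
#' @param roi A [roi_spec()].
#' @param baseline Baseline window, ms pair.
#' @return List with `reliability` (Spearman-Brown), `half_correlation`,
#'   and the per-subject `halves` matrix.
#' @export
split_half_reliability <- function(subjects, roi = roi_spec(),
                                   baseline = c(-200, 0)) {
  if (!is.list(subjects) || length(subjects) < 3L)
    stop("need at least 3 subjects")
  halves <- t(vapply(subjects, function(ep) {
    stopifnot(inherits(ep, "epoch_set"))
    n_stop <- sum(ep$condition == "successful_stop")
    n_go <- sum(ep$condition == "go")
    if (n_stop < 4L || n_go < 8L)
      stop("each subject needs >= 4 successful-stop and >= 8 go trials")
    vapply(c(1L, 0L), function(parity) {
      keep <- unlist(lapply(unique(ep$condition), function(cond) {
        idx <- which(ep$condition == cond)
        idx[seq_along(idx) %% 2L == parity]
      }))
      derive_n2(subset_epochs(ep, sort(keep)), roi, baseline)
    }, numeric(1))
  }, numeric(2)))
  r <- cor(halves[, 1], halves[, 2])
  list(reliability = spearman_brown(r), half_correlation = r,
       halves = halves)
}
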