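# Fixtures built in code: hand-sized trial logs and epoch sets.

# Build a trial log from explicit go RTs and stop-trial outcomes.
# go_rts: responded go RTs; go_omissions: count of omitted go trials;
# stop_ssd / stop_responded / stop_rts: parallel vectors over stop trials.
toy_log <- function(go_rts, go_omissions = 0, stop_ssd = numeric(0),
                    stop_responded = logical(0), stop_rts = NULL,
                    go_correct = NULL) {
  n_go <- length(go_rts) + go_omissions
  n_stop <- length(stop_ssd)
  if (is.null(stop_rts)) stop_rts <- ifelse(stop_responded, 500, NA_real_)
  if (is.null(go_correct)) go_correct <- rep(TRUE, length(go_rts))
  log <- data.frame(
    block = rep(1L, n_go + n_stop),
    trial = seq_len(n_go + n_stop),
    type = c(rep("go", n_go), rep("stop", n_stop)),
    ssd_ms = c(rep(NA_real_, n_go), stop_ssd),
    responded = c(rep(TRUE, length(go_rts)), rep(FALSE, go_omissions),
                  stop_responded),
    rt_ms = c(go_rts, rep(NA_real_, go_omissions),
              ifelse(stop_responded, stop_rts, NA_real_)),
    correct = c(go_correct, rep(NA, go_omissions), !stop_responded),
    go_finish_ms = NA_real_, stop_latency_ms = NA_real_,
    trigger_failure = NA,
    stringsAsFactors = FALSE
  )
  class(log) <- c("trial_log", "data.frame")
  log
}

# Constant-amplitude epoch set (every trial, channel, sample equal to `value`).
flat_epochs <- function(value = 5, n_stop = 4, n_go = 8, n_channels = 2,
                       sampling_rate = 250, window = c(-200, 800)) {
  n_s <- diff(window) / 1000 * sampling_rate + 1
  n <- n_stop + n_go
  epoch_set(array(value, dim = c(n, n_channels, n_s)), sampling_rate,
            window, paste0("CH", seq_len(n_channels)),
            c(rep("successful_stop", n_stop), rep("go", n_go)),
            c(rep(NA_real_, n_stop), seq(300, by = 20, length.out = n_go)))
}

# Grid mean of a Gaussian bump over the ROI window: the independent
# quadrature oracle for the injected-N2 checks.
bump_window_mean <- function(peak, center = 215, sd = 20,
                             window = c(180, 250), rate = 250,
                             epoch_window = c(-200, 800)) {
  t <- seq(epoch_window[1], epoch_window[2], by = 1000 / rate)
  sel <- t >= window[1] & t <= window[2]
  mean(peak * exp(-(t[sel] - center)^2 / (2 * sd^2)))
}
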