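test_that("behavioral summary matches hand enumeration", {
  log <- toy_log(go_rts = seq(400, 490, by = 10),
                 stop_ssd = rep(200, 4),
                 stop_responded = c(TRUE, TRUE, FALSE, FALSE),
                 stop_rts = c(420, 440, NA, NA))
  s <- summarize_behavior(log)
  expect_equal(s$p_go_omission, 0)
  expect_equal(s$p_respond_stop, 0.5)
  expect_equal(s$mean_go_rt, 445)
  expect_equal(s$mean_ssd, 200)
  expect_equal(s$mean_signal_respond_rt, 430)
  expect_equal(s$n_index, 5)
  expect_equal(s$nth_rt, 440)
})

test_that("default simulator calibration reproduces adolescent descriptives", {
  tk <- task_config(n_test_blocks = 1, trials_per_block = 20000,
                    practice_trials = 0)
  s <- summarize_behavior(simulate_session(race_params(), tk, seed = 77))
  expect_lt(abs(s$mean_go_rt - 678), 5)
  expect_lt(abs(s$p_go_omission - 0.005), 0.003)
  expect_lt(abs(s$p_choice_error - 0.05), 0.01)
})

test_that("stop-dependent summaries error on an all-go log", {
  log <- toy_log(go_rts = c(400, 500, 600))
  expect_error(summarize_behavior(log), "insufficient trials")
})

test_that("race-model screening applies the quoted bounds", {
  # p(respond|stop) = 0.20 < 0.25 -> invalid
  low_p <- toy_log(go_rts = seq(400, 490, 10), stop_ssd = rep(200, 10),
                   stop_responded = c(TRUE, TRUE, rep(FALSE, 8)),
                   stop_rts = c(420, 430, rep(NA, 8)))
  v <- check_race_assumptions(low_p)
  expect_false(v$valid)
  expect_match(paste(v$reasons, collapse = " "), "out of bounds")

  # signal-respond RT above go RT -> invalid
  slow_sr <- toy_log(go_rts = rep(650, 10), stop_ssd = rep(200, 4),
                     stop_responded = c(TRUE, TRUE, FALSE, FALSE),
                     stop_rts = c(700, 700, NA, NA))
  v2 <- check_race_assumptions(slow_sr)
  expect_false(v2$valid)
  expect_match(paste(v2$reasons, collapse = " "), "not below mean go RT")

  # p = 0.43 (3/7) with fast signal-respond RTs -> valid
  ok <- toy_log(go_rts = seq(400, 490, 10), stop_ssd = rep(200, 7),
                stop_responded = c(TRUE, TRUE, TRUE, rep(FALSE, 4)),
                stop_rts = c(410, 420, 430, rep(NA, 4)))
  v3 <- check_race_assumptions(ok)
  expect_true(v3$valid)

  # no responded stop trials: indeterminate, invalid
  none <- toy_log(go_rts = seq(400, 490, 10), stop_ssd = rep(200, 4),
                  stop_responded = rep(FALSE, 4))
  v4 <- check_race_assumptions(none)
  expect_false(v4$valid)
  expect_true(is.na(v4$signal_respond_vs_go_ok))
})

test_that("integration SSRT reproduces the hand-enumerated examples", {
  # 10 RTs 400..490, p = 0.5, mean SSD 200: n = 5, nth RT 440, SSRT 240
  a <- toy_log(go_rts = seq(400, 490, 10), stop_ssd = rep(200, 4),
               stop_responded = c(TRUE, TRUE, FALSE, FALSE),
               stop_rts = c(410, 420, NA, NA))
  ea <- estimate_ssrt(a, "integration")
  expect_equal(ea$n_index, 5)
  expect_equal(ea$finish_time, 440)
  expect_equal(ea$ssrt, 240)

  # omission replacement: {400,420,440,460} + 1 omission -> augmented
  # {400,420,440,460,460}; p = 0.6, mean SSD 150: n = 3, nth 440, SSRT 290
  b <- toy_log(go_rts = c(400, 420, 440, 460), go_omissions = 1,
               stop_ssd = rep(150, 5),
               stop_responded = c(TRUE, TRUE, TRUE, FALSE, FALSE),
               stop_rts = c(405, 410, 415, NA, NA))
  eb <- estimate_ssrt(b, "integration", override_validity = TRUE)
  expect_equal(eb$n_index, 3)
  expect_equal(eb$finish_time, 440)
  expect_equal(eb$ssrt, 290)

  # boundary p = 1: nth RT is the augmented maximum
  c_ <- toy_log(go_rts = c(400, 420, 440, 460), go_omissions = 1,
                stop_ssd = rep(100, 3), stop_responded = rep(TRUE, 3),
                stop_rts = c(405, 410, 415))
  ec <- estimate_ssrt(c_, "integration", override_validity = TRUE)
  expect_equal(ec$finish_time, 460)
  expect_equal(ec$ssrt, 460 - 100)
})

test_that("mean-method SSRT is mean go RT minus mean SSD", {
  log <- toy_log(go_rts = seq(400, 490, 10), stop_ssd = rep(200, 4),
                 stop_responded = c(TRUE, TRUE, FALSE, FALSE),
                 stop_rts = c(410, 420, NA, NA))
  e <- estimate_ssrt(log, "mean")
  expect_equal(e$ssrt, 445 - 200)
})

test_that("invalid sessions refuse estimation unless overridden", {
  bad <- toy_log(go_rts = seq(400, 490, 10), stop_ssd = rep(200, 10),
                 stop_responded = c(TRUE, rep(FALSE, 9)),
                 stop_rts = c(410, rep(NA, 9)))
  err <- tryCatch(estimate_ssrt(bad), error = identity)
  expect_s3_class(err, "stopnet_validity_error")
  expect_s3_class(err$validity, "race_validity")
  expect_s3_class(estimate_ssrt(bad, override_validity = TRUE),
                  "ssrt_estimate")
})

test_that("shifting every SSD by c shifts SSRT by exactly -c", {
  log <- toy_log(go_rts = seq(400, 490, 10), stop_ssd = rep(200, 4),
                 stop_responded = c(TRUE, TRUE, FALSE, FALSE),
                 stop_rts = c(410, 420, NA, NA))
  base <- estimate_ssrt(log)$ssrt
  for (c_shift in c(-50, 25, 130)) {
    shifted <- log
    shifted$ssd_ms <- shifted$ssd_ms + c_shift
    expect_equal(estimate_ssrt(shifted)$ssrt, base - c_shift)
  }
})

test_that("omission replacement preserves the augmented distribution shape", {
  set.seed(20)
  for (rep_i in 1:20) {
    rts <- round(runif(sample(5:30, 1), 300, 900))
    n_omit <- sample(0:3, 1)
    aug <- sort(c(rts, rep(max(rts), n_omit)))
    # adding one omission never decreases the maximum and leaves every
    # value below the previous maximum untouched
    aug2 <- sort(c(rts, rep(max(rts), n_omit + 1)))
    expect_gte(max(aug2), max(aug))
    expect_identical(aug2[aug2 < max(aug)], aug[aug < max(aug)])
    # the summary's nth RT equals direct enumeration on a matching log
    p_resp <- 0.5
    log <- toy_log(go_rts = rts, go_omissions = n_omit,
                   stop_ssd = rep(250, 4),
                   stop_responded = c(TRUE, TRUE, FALSE, FALSE),
                   stop_rts = c(310, 320, NA, NA))
    n_idx <- min(max(floor(length(aug) * p_resp + 0.5), 1), length(aug))
    expect_equal(summarize_behavior(log)$nth_rt, aug[n_idx])
  }
})

test_that("integration method recovers a constant stop latency under tracking", {
  tk <- task_config(n_test_blocks = 1, trials_per_block = 17000,
                    practice_trials = 0)
  p <- race_params(go_mu = 500, go_sigma = 50, go_tau = 100, stop_mu = 160,
                   p_go_omission = 0, p_choice_error = 0)
  log <- simulate_session(p, tk, seed = 21)
  expect_gt(sum(test_trials(log)$type == "stop"), 5000)
  e <- estimate_ssrt(log, "integration")
  expect_lt(abs(e$p_respond_stop - 0.5), 0.02)
  expect_lt(abs(e$ssrt - 160), 10)
})

test_that("the mean method is positively biased for right-skewed go RTs", {
  tk <- task_config(n_test_blocks = 1, trials_per_block = 10000,
                    practice_trials = 0, go_max_duration = 3000)
  p <- race_params(go_mu = 480, go_sigma = 90, go_tau = 200, stop_mu = 160,
                   p_go_omission = 0, p_choice_error = 0)
  log <- simulate_session(p, tk, seed = 31)
  em <- estimate_ssrt(log, "mean")$ssrt
  ei <- estimate_ssrt(log, "integration")$ssrt
  expect_gt(em, ei)
})

test_that("screening a heterogeneous batch excludes exactly the violators", {
  set.seed(99)
  stop_mus <- c(60, 160, 320, 500, 700)
  tk <- task_config(n_test_blocks = 1, trials_per_block = 400,
                    practice_trials = 0)
  for (sm in stop_mus) {
    p <- race_params(go_mu = 500, go_sigma = 50, go_tau = 100, stop_mu = sm,
                     p_go_omission = 0, p_choice_error = 0)
    log <- simulate_session(p, tk, seed = 1000 + sm)
    tl <- test_trials(log)
    st <- tl[tl$type == "stop", ]
    p_resp <- mean(st$responded)
    sr_ok <- mean(st$rt_ms[st$responded]) <
      mean(tl$rt_ms[tl$type == "go" & tl$responded])
    expect_identical(check_race_assumptions(log)$valid,
                     p_resp >= 0.25 && p_resp <= 0.75 && isTRUE(sr_ok))
  }
})
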