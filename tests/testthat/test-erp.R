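test_that("epoch containers validate their geometry", {
  expect_error(epoch_set(array(0, c(2, 1, 251)), 100, c(-200, 800), "A",
                         rep("go", 2)), "inconsistent")
  ep <- flat_epochs(5)
  expect_equal(dim(ep$data)[3], 251)
  expect_equal(length(sample_times(ep)), 251)
  expect_error(epoch_set(array(0, c(2, 1, 251)), 250, c(-200, 800), "A",
                         c("go", "weird")), "unknown condition")
})

test_that("baseline correction removes constants and preserves signals", {
  ep <- flat_epochs(5)
  out <- baseline_correct(ep)
  expect_equal(max(abs(out$data)), 0)

  # a zero-mean-over-baseline signal rides through unchanged on top of an
  # offset
  t <- sample_times(ep)
  signal <- sin(2 * pi * t / 400) - mean(sin(2 * pi * t / 400)[t <= 0])
  ep2 <- ep
  for (i in seq_len(dim(ep$data)[1]))
    for (ch in seq_len(dim(ep$data)[2]))
      ep2$data[i, ch, ] <- 5 + signal
  out2 <- baseline_correct(ep2)
  expect_equal(out2$data[1, 1, ], signal, tolerance = 1e-12)

  # ramp 0..1 over the window: output is the ramp minus its baseline mean
  ramp <- seq(0, 1, length.out = 251)
  ep3 <- ep
  for (i in seq_len(12)) for (ch in 1:2) ep3$data[i, ch, ] <- ramp
  out3 <- baseline_correct(ep3)
  expect_equal(out3$data[3, 2, ], ramp - mean(ramp[t >= -200 & t <= 0]),
               tolerance = 1e-12)

  expect_error(baseline_correct(ep, c(-500, 0)), "outside")
})

test_that("median split tags slow/fast with ties going slow", {
  ep <- flat_epochs(0, n_stop = 2, n_go = 4)
  ep$rt_ms[3:6] <- c(300, 400, 500, 600)
  tags <- median_split_go(ep)
  expect_identical(tags[3:6], c("fast", "fast", "slow", "slow"))

  ep$rt_ms[3:6] <- c(300, 400, 500, NA)
  ep$condition[6] <- "unsuccessful_stop"  # only 3 go trials remain
  ep$rt_ms[6] <- NA
  tags2 <- median_split_go(ep)
  expect_identical(tags2[3:5], c("fast", "slow", "slow"))  # tie at 400 -> slow

  ep$rt_ms[3:5] <- c(500, 500, 500)
  expect_identical(median_split_go(ep)[3:5], rep("slow", 3))

  ep_small <- flat_epochs(0, n_stop = 2, n_go = 1)
  expect_error(median_split_go(ep_small), "at least 2 go trials")
})

test_that("condition averaging is the pointwise trial mean", {
  ep <- flat_epochs(0, n_stop = 0, n_go = 2, n_channels = 1)
  ep$data[1, 1, ] <- rep(c(1, 2), length.out = 251)
  ep$data[2, 1, ] <- rep(c(3, 4), length.out = 251)
  w <- condition_erp(ep, "go")
  expect_equal(unname(w$amplitude[1, 1:2]), c(2, 3))
  expect_equal(w$n_trials, 2)

  one <- condition_erp(ep, trials = 1)
  expect_equal(one$amplitude[1, ], ep$data[1, 1, ])
  expect_equal(one$n_trials, 1)
  expect_error(condition_erp(ep, "successful_stop"), "no trials")

  # averaging n noise trials shrinks the RMS like 1/sqrt(n)
  set.seed(5)
  n <- 1000
  noisy <- epoch_set(array(rnorm(n * 1 * 251, sd = 10), c(n, 1, 251)),
                     250, c(-200, 800), "A", rep("go", n), runif(n, 300, 700))
  wave <- condition_erp(noisy, "go")
  rms <- sqrt(mean(wave$amplitude^2))
  expect_lt(abs(rms - 10 / sqrt(n)) / (10 / sqrt(n)), 0.15)
})

test_that("difference waves subtract pointwise and antisymmetrically", {
  ep <- flat_epochs(0)
  a <- condition_erp(ep, "go"); b <- condition_erp(ep, "go")
  a$amplitude[] <- -1; b$amplitude[] <- 1
  d <- difference_wave(a, b)
  expect_true(all(d$amplitude == -2))
  expect_true(all(difference_wave(a, a)$amplitude == 0))
  flipped <- difference_wave(b, a)
  expect_equal(d$amplitude + flipped$amplitude,
               matrix(0, nrow(d$amplitude), ncol(d$amplitude)),
               ignore_attr = TRUE)
  b$channels <- rev(b$channels)
  expect_error(difference_wave(a, b), "mismatch")
})

test_that("ROI mean amplitude uses inclusive sample-grid endpoints", {
  ep <- flat_epochs(-2)
  w <- condition_erp(ep, "go")
  expect_equal(roi_mean_amplitude(w, roi_spec(c("CH1", "CH2"))), -2)

  # at 250 Hz the 180-250 ms window holds samples 180, 184, ..., 248
  t <- sample_times(w)
  expect_equal(sum(t >= 180 & t <= 250), 18)
  expect_equal(t[t >= 180 & t <= 250], seq(180, 248, by = 4))

  # Gaussian bump against the quadrature oracle
  bump <- -3 * exp(-(t - 215)^2 / (2 * 20^2))
  w$amplitude[1, ] <- bump; w$amplitude[2, ] <- bump
  expect_equal(roi_mean_amplitude(w, roi_spec(c("CH1", "CH2"))),
               bump_window_mean(-3), tolerance = 1e-12)

  expect_error(roi_mean_amplitude(w, roi_spec("nope")), "absent")
  expect_error(roi_mean_amplitude(w, roi_spec("CH1", c(900, 950))),
               "outside")
})

test_that("noiseless injected N2 is recovered exactly and linearly", {
  ep <- generate_epoch_set(n2_amplitude = -2, noise_sd = 0, seed = 1)
  expect_equal(derive_n2(ep), bump_window_mean(-2), tolerance = 1e-6)
  expect_equal(derive_n2(ep), attr(ep, "true_n2_window_mean"),
               tolerance = 1e-6)
  # linearity: scaling all epochs by c scales the measure by c
  ep3 <- ep
  ep3$data <- ep$data * 3
  expect_equal(derive_n2(ep3), 3 * derive_n2(ep), tolerance = 1e-9)
})

test_that("epoch generator respects trial counts and is unbiased", {
  ep <- generate_epoch_set(n2_amplitude = -2, n_stop = 35, n_go = 144,
                           noise_sd = 10, seed = 2)
  expect_equal(sum(ep$condition == "successful_stop"), 35)
  expect_equal(sum(ep$condition == "go"), 144)

  # across subjects the derived N2 is unbiased for the injected window mean
  set.seed(7)
  n2s <- vapply(1:60, function(i)
    derive_n2(generate_epoch_set(n2_amplitude = -2, n_stop = 12, n_go = 24,
                                 noise_sd = 10,
                                 channels = paste0("ROI", 1:6))),
    numeric(1))
  expect_lt(abs(mean(n2s) - bump_window_mean(-2)), 0.35)
})

test_that("split-half reliability behaves at its anchors", {
  expect_equal(spearman_brown(0.5), 2 * 0.5 / 1.5)

  # halves identical by construction -> reliability 1
  set.seed(11)
  subjects <- lapply(1:8, function(i) {
    half <- generate_epoch_set(n2_amplitude = -i, n_stop = 4, n_go = 8,
                               noise_sd = 3, channels = paste0("ROI", 1:2),
                               roi_channels = paste0("ROI", 1:2))
    # duplicate every trial so odd/even halves coincide exactly
    idx <- rep(seq_along(half$condition), each = 2)
    epoch_set(half$data[idx, , , drop = FALSE], half$sampling_rate,
              half$epoch_window, half$channels, half$condition[idx],
              half$rt_ms[idx])
  })
  roi2 <- roi_spec(paste0("ROI", 1:2))
  expect_equal(split_half_reliability(subjects, roi2)$reliability, 1,
               tolerance = 1e-9)

  # pure noise, no subject-level signal -> reliability near zero
  set.seed(12)
  noise_subjects <- lapply(1:200, function(i)
    generate_epoch_set(n2_amplitude = 0, n_stop = 8, n_go = 8,
                       noise_sd = 10, go_template_amp = 0,
                       channels = paste0("ROI", 1:2),
                       roi_channels = paste0("ROI", 1:2)))
  r0 <- split_half_reliability(noise_subjects, roi2)$half_correlation
  expect_lt(abs(r0), 0.1)

  expect_error(split_half_reliability(subjects[1:2]), "at least 3")
})

test_that("reliability grows with between-subject signal variance", {
  roi2 <- roi_spec(paste0("ROI", 1:2))
  rel_at <- function(amp_sd, seed) {
    set.seed(seed)
    subjects <- lapply(1:60, function(i)
      generate_epoch_set(n2_amplitude = rnorm(1, -2, amp_sd), n_stop = 8,
                         n_go = 8, noise_sd = 10,
                         channels = paste0("ROI", 1:2),
                         roi_channels = paste0("ROI", 1:2)))
    split_half_reliability(subjects, roi2)$reliability
  }
  rels <- c(rel_at(0, 21), rel_at(3, 22), rel_at(9, 23))
  expect_true(all(diff(rels) > 0))
})
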