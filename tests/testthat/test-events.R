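test_that("noiseless minis are recovered perfectly", {
  g <- gen_mini_trace(synth_config(3, 10000, 30, noise_sd = 0), rate = 2,
                      amp_mean = 20)
  ev <- detect_minis(g$trace)
  m <- match_events(ev$onset_s, g$events$onset_s)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
})

test_that("pure noise produces essentially no detections at multiplier 5", {
  g <- gen_mini_trace(synth_config(7, 10000, 300, noise_sd = 2), rate = 0,
                      amp_mean = 20)
  ev <- detect_minis(g$trace, threshold_multiplier = 5, characterize = FALSE)
  # Gaussian tail oracle: the chance that the 0.5-ms-smoothed noise stays
  # above 5 SD for a millisecond is vanishing; expected false alarms << 1
  p_tail <- stats::pnorm(5, lower.tail = FALSE)
  expect_lt(length(g$trace$samples) * p_tail / 10, 1)  # per ~1 ms run
  expect_lte(nrow(ev), 1)
})

test_that("raising the threshold never increases the event count", {
  g <- gen_mini_trace(synth_config(9, 10000, 60, noise_sd = 2), rate = 5,
                      amp_mean = 20)
  counts <- vapply(c(2.5, 3.5, 5, 7, 10), function(m) {
    nrow(detect_minis(g$trace, threshold_multiplier = m, characterize = FALSE))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("event characterization recovers template kinetics and scales linearly", {
  fs <- 10000
  tpl <- biexp_template(2, 8, fs)
  x <- numeric(20 * fs)
  x[(2 * fs):(2 * fs + length(tpl) - 1)] <- -20 * tpl
  tr <- ephys_trace(x, fs, "pA")
  ev <- characterize_event(tr, 2, polarity = "inward")
  expect_equal(ev$amplitude_pA, 20, tolerance = 0.01)
  expect_equal(ev$decay_ms, 8, tolerance = 0.05 * 8)
  expect_false(ev$flagged)
  tr2 <- tr; tr2$samples <- tr2$samples * 2
  ev2 <- characterize_event(tr2, 2, polarity = "inward")
  expect_equal(ev2$amplitude_pA, 2 * ev$amplitude_pA, tolerance = 1e-9)
  expect_equal(ev2$rise_ms, ev$rise_ms, tolerance = 1e-9)
  expect_equal(ev2$decay_ms, ev$decay_ms, tolerance = 1e-9)
})

test_that("a step-like event without decay is flagged non-convergent", {
  fs <- 10000
  x <- numeric(20 * fs)
  x[(2 * fs):length(x)] <- -20  # step, never decays
  tr <- ephys_trace(x, fs, "pA")
  ev <- characterize_event(tr, 2, polarity = "inward")
  expect_true(ev$flagged)
  expect_true(is.na(ev$decay_ms))
})

test_that("mini summaries do exact frequency arithmetic in both unit conventions", {
  ev <- data.frame(onset_s = seq_len(1500) / 5, peak_s = seq_len(1500) / 5,
                   amplitude_pA = 20, rise_ms = 2, decay_ms = 8,
                   flagged = FALSE)
  s1 <- summarize_minis(ev, duration = 300, frequency_unit = "per_s")
  expect_equal(s1$frequency, 5.0)
  expect_equal(s1$frequency * 300, s1$n_events)
  s2 <- summarize_minis(ev[1:40, ], duration = 300, frequency_unit = "per_min")
  expect_equal(s2$frequency, 8.0)
  empty <- ev[0, ]
  s0 <- summarize_minis(empty, duration = 300)
  expect_equal(s0$frequency, 0)
  expect_true(is.na(s0$mean_amplitude_pA))
})

test_that("detected amplitudes are unbiased on seeded synthetic minis", {
  g <- gen_mini_trace(synth_config(42, 10000, 120, noise_sd = 2), rate = 5,
                      amp_mean = 20)
  sm <- summarize_minis(detect_minis(g$trace))
  expect_lt(abs(sm$mean_amplitude_pA / 20 - 1), 0.05)
})

test_that("saturated traces are refused with a diagnostic", {
  g <- gen_mini_trace(synth_config(4, 10000, 30, noise_sd = 2), rate = 5,
                      amp_mean = 50)
  tr <- g$trace
  tr$samples <- pmax(tr$samples, -30)
  expect_error(detect_minis(tr), "saturated")
})

test_that("paired-pulse ratio handles identity, depression, and overlap", {
  fs <- 10000
  tpl <- biexp_template(0.5, 30, fs, length_ms = 400)
  mk <- function(a1, a2, interval = 0.05) {
    x <- numeric(fs)
    s1 <- round(0.2 * fs) + 1L
    s2 <- s1 + round(interval * fs)
    x[s1:(s1 + length(tpl) - 1)] <- x[s1:(s1 + length(tpl) - 1)] - a1 * tpl
    x[s2:(s2 + length(tpl) - 1)] <- x[s2:(s2 + length(tpl) - 1)] - a2 * tpl
    ephys_trace(x, fs, "pA")
  }
  # identical responses, far enough apart not to overlap
  expect_equal(as.numeric(paired_pulse_ratio(mk(100, 100, 0.4),
                                             c(0.2, 0.6),
                                             response_window_ms = 100)),
               1.0, tolerance = 1e-4)
  # depression regime
  expect_equal(as.numeric(paired_pulse_ratio(mk(100, 80, 0.4), c(0.2, 0.6),
                                             response_window_ms = 100)),
               0.8, tolerance = 1e-4)
  # 50-ms interval with overlapping decay: residual subtraction keeps the
  # ratio within 2%
  expect_equal(as.numeric(paired_pulse_ratio(mk(100, 150), c(0.2, 0.25))),
               1.5, tolerance = 0.02 * 1.5)
  # scale invariance
  tr <- mk(100, 150)
  tr2 <- tr; tr2$samples <- tr2$samples * 3.7
  expect_equal(as.numeric(paired_pulse_ratio(tr, c(0.2, 0.25))),
               as.numeric(paired_pulse_ratio(tr2, c(0.2, 0.25))),
               tolerance = 1e-12)
  # zero first peak is an error
  flat <- ephys_trace(numeric(fs), fs, "pA")
  expect_error(paired_pulse_ratio(flat, c(0.2, 0.25)), "undefined")
  expect_error(paired_pulse_ratio(tr, c(0.25, 0.2)), "follow")
})
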