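test_that("a flat recording yields zero spikes and a missing baseline errors", {
  rec <- eeg_recording(numeric(40 * 2000), 2000)
  sp <- detect_spikes(rec, spike_detection_params(baseline_interval = c(0, 30)))
  expect_identical(nrow(sp), 0L)
  expect_error(detect_spikes(rec, spike_detection_params()), "baseline")
  expect_error(detect_spikes(rec,
                             spike_detection_params(baseline_interval = c(0, 5))),
               "10 s")
})

test_that("planted spikes at 8x SD are found; slow waves are rejected by the duration rule", {
  spike_t <- planted_spike_times(31)
  gt <- eeg_ground_truth(spike_times = spike_t, spike_amplitudes = 8 * 25,
                         artifact_intervals = rbind(c(31, 31.4), c(33, 33.5)))
  rec <- gen_eeg(synth_config(31, 2000, 120, noise_sd = 25), gt,
                 artifact_amplitude = 10 * 25)$recording
  sp <- detect_spikes(rec, spike_detection_params(baseline_interval = c(0, 30)))
  m <- match_events(sp$time_s, spike_t, tol = 0.05)
  expect_gte(m$recall, 0.95)
  false_det <- sum(vapply(sp$time_s, function(o) {
    !any(abs(spike_t - o) <= 0.05)
  }, logical(1)))
  expect_lte(false_det, 2)
  # nothing detected inside the planted > 200 ms artifacts
  expect_false(any(sp$time_s >= 31 & sp$time_s <= 31.4))
  expect_false(any(sp$time_s >= 33 & sp$time_s <= 33.5))
  expect_gte(attr(sp, "n_rejected_artifacts"), 2)
  # every retained waveform respects the duration rule
  expect_true(all(sp$duration_ms <= 200))
})

test_that("spike counts are non-increasing in the threshold multiplier", {
  spike_t <- planted_spike_times(44)
  gt <- eeg_ground_truth(spike_times = spike_t, spike_amplitudes = 6 * 25)
  rec <- gen_eeg(synth_config(44, 2000, 120, noise_sd = 25), gt)$recording
  counts <- vapply(c(2, 3, 4, 5, 7), function(k) {
    nrow(detect_spikes(rec, spike_detection_params(
      threshold_multiplier = k, baseline_interval = c(0, 30))))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("discharge grouping follows the three-in-200-ms rule", {
  d <- group_discharges(c(0, 0.1, 0.25, 1.0, 1.15, 2.0))
  expect_identical(nrow(d), 1L)
  expect_identical(d$n_spikes, 3L)
  expect_equal(d$onset_s, 0)
  expect_equal(d$offset_s, 0.25)
  expect_identical(nrow(group_discharges(c(1, 1.1))), 0L)
  expect_identical(nrow(group_discharges(numeric())), 0L)
  expect_error(group_discharges(c(2, 1)), "sorted")
})

test_that("discharge grouping matches the brute-force oracle on random trains", {
  for (s in 1:30) {
    times <- withr::with_seed(s, sort(stats::runif(500, 0, 60)))
    got <- group_discharges(times)
    want <- brute_force_discharges(times)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$onset_s, want$onset_s)
    expect_equal(got$offset_s, want$offset_s)
    expect_identical(got$n_spikes, want$n_spikes)
  }
})

test_that("discharge rate normalizes to hours while preserving the raw count", {
  r <- discharge_rate(data.frame(onset_s = 1:12), 24 * 3600)
  expect_equal(r$rate_per_hour, 0.5)
  expect_identical(r$n_discharges, 12L)
  expect_equal(discharge_rate(0, 3600)$rate_per_hour, 0)
  expect_error(discharge_rate(3, 0), "> 0")
})

test_that("planted discharge schedules are recovered exactly at high SNR", {
  cl_starts <- seq(35, 110, by = 5)
  spike_t <- sort(as.vector(outer(c(0, 0.1, 0.2), cl_starts, "+")))
  gt <- eeg_ground_truth(spike_times = spike_t, spike_amplitudes = 8 * 25)
  rec <- gen_eeg(synth_config(91, 2000, 120, noise_sd = 25), gt)$recording
  sp <- detect_spikes(rec, spike_detection_params(baseline_interval = c(0, 30)))
  d <- group_discharges(sp)
  expect_identical(nrow(d), length(cl_starts))
})

test_that("a pure tone concentrates its relative power in its own band", {
  fs <- 2000
  x <- 50 * sin(2 * pi * 6 * (0:(18 * fs - 1)) / fs)
  bp <- relative_band_powers(eeg_recording(x, fs), rbind(c(0, 9), c(9, 18)))
  expect_gte(bp$relative[["theta"]], 0.99)
})

test_that("relative band powers are normalized per epoch to machine precision", {
  rec <- eeg_recording(withr::with_seed(2, rnorm(90 * 2000, 0, 20)), 2000)
  ep <- cbind(seq(0, 81, by = 9), seq(9, 90, by = 9))
  bp <- relative_band_powers(rec, ep)
  expect_true(all(abs(rowSums(bp$per_epoch_relative) - 1) < 1e-12))
  expect_identical(bp$n_epochs, 10L)
})

test_that("epochs overlapping annotated artifacts are rejected, all-rejected errors", {
  ann <- data.frame(start_s = 4, end_s = 5, label = "artifact")
  rec <- eeg_recording(withr::with_seed(3, rnorm(30 * 2000, 0, 20)), 2000,
                       annotations = ann)
  expect_warning(bp <- relative_band_powers(rec, rbind(c(0, 9), c(10, 19))),
                 "artifact")
  expect_identical(bp$n_epochs, 1L)
  expect_error(suppressWarnings(relative_band_powers(rec, rbind(c(0, 9)))),
               "rejected")
})

test_that("generated band mixtures are recovered through the spectral pipeline", {
  mix <- c(0.4, 0.3, 0.2, 0.1)
  rec <- gen_eeg(synth_config(104, 2000, 450, noise_sd = 30),
                 eeg_ground_truth(band_mix = mix))$recording
  ep <- cbind(seq(0, 441, by = 9), seq(9, 450, by = 9))
  bp <- relative_band_powers(rec, ep, window_s = 6)
  expect_lt(max(abs(bp$relative - mix)), 0.03)
})
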