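test_that("generators are byte-identical under a fixed seed", {
  cfg <- synth_config(11, 5000, 0.5, noise_sd = 5)
  gt <- clamp_ground_truth(-70, 10, 3, 4, seq(-100, -40, by = 10))
  a <- gen_iv_protocol(cfg, gt)
  b <- gen_iv_protocol(cfg, gt)
  expect_identical(a$traces, b$traces)

  cfgm <- synth_config(11, 10000, 20, noise_sd = 2)
  expect_identical(gen_mini_trace(cfgm, 5, 20), gen_mini_trace(cfgm, 5, 20))

  cfge <- synth_config(11, 2000, 30, noise_sd = 25)
  gte <- eeg_ground_truth(spike_times = c(5, 12), spike_amplitudes = 200)
  expect_identical(gen_eeg(cfge, gte), gen_eeg(cfge, gte))
})

test_that("peak GABA current vanishes at zero driving force", {
  cfg <- synth_config(1, 5000, 0.5, noise_sd = 0)
  gt <- clamp_ground_truth(-70, 0, 2, 5, c(-80, -70, -60))
  iv <- gen_iv_protocol(cfg, gt)
  pk <- peak_gaba_current(iv$traces[["-70"]], 0.1, response_window = 0.25)
  expect_lt(abs(as.numeric(pk)), 1e-9)
})

test_that("with Rs = 0 and no noise the peak I-V is linear through E_rev", {
  cfg <- synth_config(1, 5000, 0.5, noise_sd = 0)
  gt <- clamp_ground_truth(-72.5, 0, 2, 5, seq(-100, -40, by = 10))
  iv <- gen_iv_protocol(cfg, gt)
  tab <- measure_iv(iv$traces, 0.1, R_s = 0, response_window = 0.25)
  fit <- fit_reversal(tab)
  expect_lt(abs(fit$E_rev - (-72.5)), 1e-9)
  expect_lt(fit$residual_rms_pA, 1e-9)
})

test_that("series resistance shifts the uncorrected I-V exactly as the circuit oracle predicts", {
  cfg <- synth_config(1, 5000, 0.5, noise_sd = 0)
  gt <- clamp_ground_truth(-70, 10, 8, 4, seq(-100, -40, by = 10),
                           leak_reversal = -50)
  iv <- gen_iv_protocol(cfg, gt)
  for (v in gt$command_schedule) {
    pk <- peak_gaba_current(iv$traces[[as.character(v)]], 0.1,
                            response_window = 0.25)
    orc <- circuit_peak_oracle(v, 8, -50, 4, -70, 10)
    expect_lt(abs(as.numeric(pk) - orc$response), 1e-6)
    expect_lt(abs(attr(pk, "I_total") - orc$total), 1e-6)
  }
  # the raw (uncorrected) zero crossing is biased away from E_rev
  tab <- measure_iv(iv$traces, 0.1, R_s = 10, response_window = 0.25)
  fit_raw <- fit_reversal(tab, use = "V_com")
  expect_gt(abs(fit_raw$E_rev - (-70)), 0.1)
  # and the oracle points predict the same biased crossing
  orc_tab <- t(vapply(gt$command_schedule, function(v) {
    o <- circuit_peak_oracle(v, 8, -50, 4, -70, 10)
    c(v, o$response)
  }, numeric(2)))
  fit_orc <- stats::lm(orc_tab[, 2] ~ orc_tab[, 1])
  e_orc <- -stats::coef(fit_orc)[1] / stats::coef(fit_orc)[2]
  expect_lt(abs(fit_raw$E_rev - e_orc), 1e-6)
})

test_that("generator refuses a command schedule that does not span the reversal", {
  expect_error(clamp_ground_truth(-70, 0, 2, 5, c(-60, -50, -40)),
               "span")
  expect_error(clamp_ground_truth(-70, 0, 2, 5, c(-80, -75)),
               "3 distinct")
})

test_that("Poisson event counts fall in the 99% interval and truth is conserved", {
  cfg <- synth_config(17, 10000, 300, noise_sd = 2)
  g <- gen_mini_trace(cfg, rate = 5, amp_mean = 20)
  lim <- stats::qpois(c(0.005, 0.995), 5 * 300)
  expect_gte(nrow(g$events), lim[1])
  expect_lte(nrow(g$events), lim[2])
  expect_true(!is.unsorted(g$events$onset_s))
})

test_that("rate zero gives pure noise and an empty truth list", {
  g <- gen_mini_trace(synth_config(3, 10000, 15, noise_sd = 2), rate = 0,
                      amp_mean = 20)
  expect_identical(nrow(g$events), 0L)
  expect_lt(abs(stats::sd(g$trace$samples) - 2), 0.1)
})

test_that("a single noiseless planted event has max deviation equal to its amplitude", {
  g <- gen_mini_trace(synth_config(8, 10000, 15, noise_sd = 0), rate = 0.1,
                      amp_mean = 20)
  skip_if(nrow(g$events) == 0)  # Poisson draw: retry with denser rate below
  expect_equal(max(abs(g$trace$samples)), 20, tolerance = 1e-12)
})

test_that("invalid mini kinetics are refused", {
  cfg <- synth_config(1, 10000, 15, noise_sd = 0)
  expect_error(gen_mini_trace(cfg, 1, 20, rise = 8, decay = 8), "kinetics")
  expect_error(biexp_template(5, 2, 10000), "kinetics")
})

test_that("tonic generator plants an exact, fully settled baseline step", {
  g <- gen_tonic_trace(synth_config(12, 10000, 120, noise_sd = 0),
                       tonic_shift = 20, antagonist_onset = 60, mini_rate = 0)
  pre <- g$trace$samples[1:(55 * 10000)]
  post <- g$trace$samples[(70 * 10000):(120 * 10000)]
  expect_equal(mean(post) - mean(pre), 20, tolerance = 1e-12)
  # zero shift: pre/post means equal within noise
  g0 <- gen_tonic_trace(synth_config(13, 10000, 60, noise_sd = 2),
                        tonic_shift = 0, antagonist_onset = 30, mini_rate = 0)
  pre0 <- mean(g0$trace$samples[1:(25 * 10000)])
  post0 <- mean(g0$trace$samples[(35 * 10000):(60 * 10000)])
  expect_lt(abs(post0 - pre0), 4 * 2 / sqrt(25 * 10000) * 50)
  expect_error(gen_tonic_trace(synth_config(1, 1000, 10), 10,
                               antagonist_onset = 20), "inside")
})

test_that("EEG generator honours its ground-truth contract", {
  gt <- eeg_ground_truth(spike_times = planted_spike_times(5, n = 50),
                         spike_amplitudes = 200)
  cfg <- synth_config(5, 2000, 120, noise_sd = 25)
  out <- gen_eeg(cfg, gt)
  expect_identical(length(out$ground_truth$spike_times), 50L)
  expect_identical(out$ground_truth, gt)
  # spikes inside artifacts refused; short artifacts refused
  expect_error(eeg_ground_truth(spike_times = 10, spike_amplitudes = 100,
                                artifact_intervals = rbind(c(9.5, 10.5))),
               "outside artifact")
  expect_error(eeg_ground_truth(artifact_intervals = rbind(c(5, 5.1))),
               "200 ms")
  expect_warning(eeg_ground_truth(band_mix = c(1, 1, 1, 1)), "normaliz")
})

test_that("flat band mix yields relative powers near the bandwidth fractions", {
  cfg <- synth_config(21, 2000, 90, noise_sd = 30)
  rec <- gen_eeg(cfg, eeg_ground_truth(band_mix = c(3, 5, 4, 17) / 29))$recording
  ep <- cbind(seq(0, 81, by = 9), seq(9, 90, by = 9))
  bp <- relative_band_powers(rec, ep)
  expect_lt(max(abs(bp$relative - c(3, 5, 4, 17) / 29)), 0.02)
})

test_that("realized spectral content matches band_mix at native resolution", {
  mix <- c(0.4, 0.3, 0.2, 0.1)
  rec <- gen_eeg(synth_config(33, 2000, 90, noise_sd = 30),
                 eeg_ground_truth(band_mix = mix))$recording
  x <- rec$signal
  pw <- Mod(stats::fft(x))^2
  fr <- (seq_along(x) - 1) / length(x) * 2000
  bp <- vapply(list(c(1, 4), c(4, 9), c(9, 13), c(13, 30)), function(b) {
    sum(pw[fr >= b[1] & fr < b[2]])
  }, numeric(1))
  expect_lt(max(abs(bp / sum(bp) - mix)), 0.02)
})
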