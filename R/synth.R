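#' Synthetic-data generator configuration
#'
#' Shared configuration for all seeded generators.  A fixed seed makes every
#' generator byte-identical across calls; each generator draws from its own
#' sub-stream derived from the root seed so stages can be re-run
#' independently without perturbing one another.
#'
#' @param seed Integer root seed.
#' @param sampling_rate Sampling rate in Hz.
#' @param duration Duration in seconds.
#' @param noise_sd Additive Gaussian noise SD, in pA (clamp traces) or
#'   microvolts (EEG).
#' @return An object of class `"synth_config"`.
#' @examples
#' cfg <- synth_config(seed = 1, sampling_rate = 10000, duration = 10, noise_sd = 2)
#' @export
synth_config <- function(seed, sampling_rate, duration, noise_sd = 0) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (sampling_rate <= 0) stop("'sampling_rate' must be > 0")
  if (duration <= 0) stop("'duration' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(seed = as.integer(seed),
                 sampling_rate = sampling_rate,
                 duration = duration,
                 noise_sd = noise_sd),
            class = "synth_config")
}

# derived sub-stream seed per generator, kept inside 32-bit integer range
.substream <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

#' Normalized difference-of-exponentials transient template
#'
#' `f(t) = exp(-t / decay) - exp(-t / rise)`, scaled to unit peak.  Used for
#' both miniature postsynaptic currents and evoked GABA conductances.
#'
#' @param rise,decay Rise and decay time constants in ms (`decay > rise > 0`).
#' @param sampling_rate Hz.
#' @param length_ms Template length in ms (default covers 8 decay constants).
#' @return Numeric vector starting at the event onset, unit peak.
#' @export
biexp_template <- function(rise, decay, sampling_rate,
                           length_ms = rise + 8 * decay) {
  if (rise <= 0 || decay <= 0) stop("rise and decay must be > 0")
  if (decay <= rise) stop("invalid kinetics: decay must exceed rise")
  n <- max(2L, ceiling(length_ms / 1000 * sampling_rate))
  t_ms <- (seq_len(n) - 1L) / sampling_rate * 1000
  f <- exp(-t_ms / decay) - exp(-t_ms / rise)
  # unit peak on the sampling grid, so a planted event of amplitude A has a
  # sampled extremum of exactly A
  f / max(f)
}

# add template 'tpl' scaled by 'amps' at sample indices 'starts' (in place)
.add_events <- function(x, starts, tpl, amps) {
  n <- length(x)
  m <- length(tpl)
  for (k in seq_along(starts)) {
    i1 <- starts[k]
    if (i1 > n) next
    i2 <- min(n, i1 + m - 1L)
    x[i1:i2] <- x[i1:i2] + amps[k] * tpl[seq_len(i2 - i1 + 1L)]
  }
  x
}

#' Ground truth for a synthetic stepped-potential GABA protocol
#'
#' Describes the simulated cell and protocol: a leak conductance, a transient
#' GABA-A conductance with a true reversal potential, and an uncompensated
#' series resistance producing the voltage error the correction
#' `V_corr = V_com - I_clamp x R_s` undoes.
#'
#' @param true_E_rev True GABA reversal potential (mV).
#' @param true_Rs Series resistance (megaohm).
#' @param leak_conductance Leak conductance (nS).
#' @param gaba_peak_conductance Peak GABA conductance (nS).
#' @param command_schedule Command potentials (mV); needs >= 3 distinct
#'   values spanning `true_E_rev`.
#' @param leak_reversal Leak reversal potential (mV).
#' @param stim_time GABA application time within each sweep (s).
#' @param rise,decay GABA conductance kinetics, time constants in ms.
#' @return An object of class `"clamp_ground_truth"`.
#' @export
clamp_ground_truth <- function(true_E_rev, true_Rs, leak_conductance,
                               gaba_peak_conductance, command_schedule,
                               leak_reversal = -70, stim_time = 0.1,
                               rise = 2, decay = 30) {
  if (true_Rs < 0) stop("series resistance must be >= 0")
  if (leak_conductance < 0 || gaba_peak_conductance <= 0) {
    stop("conductances must be non-negative (GABA peak > 0)")
  }
  sched <- sort(unique(as.numeric(command_schedule)))
  if (length(sched) < 3) {
    stop("command schedule needs >= 3 distinct potentials")
  }
  if (min(sched) >= true_E_rev || max(sched) <= true_E_rev) {
    stop("command schedule must span true_E_rev; the reversal is otherwise unidentifiable")
  }
  structure(list(true_E_rev = true_E_rev, true_Rs = true_Rs,
                 leak_conductance = leak_conductance,
                 gaba_peak_conductance = gaba_peak_conductance,
                 command_schedule = as.numeric(command_schedule),
                 leak_reversal = leak_reversal, stim_time = stim_time,
                 rise = rise, decay = decay),
            class = "clamp_ground_truth")
}

#' Simulate a stepped-potential GABA-response protocol
#'
#' For each command potential, solves the clamp circuit per sample:
#' the membrane sees `V = V_com - I * Rs` while
#' `I = g_leak (V - E_leak) + g_gaba(t) (V - E_rev)`, which is linear and
#' solved in closed form.  Units: nS x mV = pA; pA x megaohm = microvolt
#' (scaled to mV internally).  Gaussian noise of `cfg$noise_sd` pA is added.
#'
#' @param cfg A [synth_config()].  `cfg$duration` is the sweep length.
#' @param gt A [clamp_ground_truth()].
#' @return List with `traces` (named list of [ephys_trace()], one per
#'   command potential, names the potentials in mV) and `ground_truth`
#'   (the input `gt`, unchanged).
#' @examples
#' cfg <- synth_config(1, 5000, 0.5, noise_sd = 0)
#' gt <- clamp_ground_truth(-70, 0, 2, 5, seq(-100, -40, by = 10))
#' iv <- gen_iv_protocol(cfg, gt)
#' @export
gen_iv_protocol <- function(cfg, gt) {
  stopifnot(inherits(cfg, "synth_config"), inherits(gt, "clamp_ground_truth"))
  if (gt$stim_time >= cfg$duration) stop("stim_time must fall inside the sweep")
  n <- round(cfg$duration * cfg$sampling_rate)
  tpl <- biexp_template(gt$rise, gt$decay, cfg$sampling_rate)
  g_gaba <- numeric(n)
  i_stim <- floor(gt$stim_time * cfg$sampling_rate) + 1L
  g_gaba <- .add_events(g_gaba, i_stim, tpl, gt$gaba_peak_conductance)
  rs <- gt$true_Rs * 1e-3  # megaohm -> mV per pA
  traces <- withr::with_seed(.substream(cfg$seed, 11L), {
    lapply(gt$command_schedule, function(v_com) {
      i <- (gt$leak_conductance * (v_com - gt$leak_reversal) +
              g_gaba * (v_com - gt$true_E_rev)) /
        (1 + rs * (gt$leak_conductance + g_gaba))
      if (cfg$noise_sd > 0) i <- i + stats::rnorm(n, 0, cfg$noise_sd)
      ephys_trace(i, cfg$sampling_rate, "pA",
                  channel = sprintf("Vcom_%+g_mV", v_com))
    })
  })
  names(traces) <- as.character(gt$command_schedule)
  list(traces = traces, ground_truth = gt)
}

#' Simulate a miniature postsynaptic current trace
#'
#' Homogeneous Poisson event times; each event is a difference-of-exponentials
#' transient of unit peak scaled to its amplitude, superimposed on white
#' Gaussian noise.
#'
#' @param cfg A [synth_config()].
#' @param rate Event rate (events/s, >= 0).
#' @param amp_mean Mean event amplitude (pA, magnitude).
#' @param rise,decay Event kinetics, time constants in ms (`decay > rise`).
#' @param amp_cv Coefficient of variation of event amplitudes (default 0:
#'   fixed amplitude).
#' @param polarity `"inward"` (negative deflections) or `"outward"`.
#' @param holding_current Constant baseline current (pA).
#' @return List with `trace` (an [ephys_trace()]) and `events`
#'   (data.frame `onset_s`, `amplitude_pA`, sorted by onset).
#' @export
gen_mini_trace <- function(cfg, rate, amp_mean, rise = 2, decay = 8,
                           amp_cv = 0, polarity = c("inward", "outward"),
                           holding_current = 0) {
  stopifnot(inherits(cfg, "synth_config"))
  polarity <- match.arg(polarity)
  if (rate < 0) stop("'rate' must be >= 0")
  if (decay <= rise) stop("invalid kinetics: decay must exceed rise")
  n <- round(cfg$duration * cfg$sampling_rate)
  sgn <- if (polarity == "inward") -1 else 1
  tpl <- biexp_template(rise, decay, cfg$sampling_rate)
  out <- withr::with_seed(.substream(cfg$seed, 23L), {
    n_ev <- if (rate > 0) stats::rpois(1, rate * cfg$duration) else 0L
    onsets <- sort(stats::runif(n_ev, 0, cfg$duration))
    amps <- rep(amp_mean, n_ev)
    if (amp_cv > 0 && n_ev > 0) {
      amps <- amps * pmax(0.05, stats::rnorm(n_ev, 1, amp_cv))
    }
    x <- rep(holding_current, n)
    x <- .add_events(x, floor(onsets * cfg$sampling_rate) + 1L, tpl, sgn * amps)
    if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
    list(x = x, onsets = onsets, amps = amps)
  })
  list(trace = ephys_trace(out$x, cfg$sampling_rate, "pA", channel = "Im"),
       events = data.frame(onset_s = out$onsets, amplitude_pA = out$amps))
}

#' Simulate a tonic-current antagonist-application trace
#'
#' Baseline holding current carries superimposed miniature GABA-A events
#' until the antagonist arrives at `antagonist_onset`; the antagonist
#' suppresses the minis and shifts the baseline by `tonic_shift` pA toward
#' 0 (block of a standing inward tonic current at negative holding).  The
#' shift settles smoothly over `settle_duration` seconds and is complete —
#' exactly `tonic_shift` — thereafter.
#'
#' @param cfg A [synth_config()].
#' @param tonic_shift Baseline shift (pA, positive = outward shift).
#' @param antagonist_onset Antagonist arrival time (s), inside the trace.
#' @param mini_rate Miniature event rate before the antagonist (events/s).
#' @param mini_amp,rise,decay Miniature event amplitude (pA) and kinetics (ms).
#' @param holding_current Holding current before the antagonist (pA).
#' @param settle_duration Settling time of the baseline shift (s).
#' @return List with `trace` and `truth` (list: `tonic_shift`,
#'   `antagonist_onset`, `settle_duration`, `mini_onsets`).
#' @export
gen_tonic_trace <- function(cfg, tonic_shift, antagonist_onset, mini_rate = 0,
                            mini_amp = 20, rise = 2, decay = 8,
                            holding_current = -60, settle_duration = 2) {
  stopifnot(inherits(cfg, "synth_config"))
  if (antagonist_onset <= 0 || antagonist_onset >= cfg$duration) {
    stop("'antagonist_onset' must lie strictly inside the trace")
  }
  n <- round(cfg$duration * cfg$sampling_rate)
  tt <- (seq_len(n) - 1L) / cfg$sampling_rate
  # raised-cosine settling: 0 before onset, tonic_shift after onset + settle
  u <- (tt - antagonist_onset) / settle_duration
  ramp <- ifelse(u <= 0, 0, ifelse(u >= 1, 1, 0.5 * (1 - cos(pi * u))))
  x <- holding_current + tonic_shift * ramp
  tpl <- biexp_template(rise, decay, cfg$sampling_rate)
  out <- withr::with_seed(.substream(cfg$seed, 37L), {
    n_ev <- if (mini_rate > 0) stats::rpois(1, mini_rate * antagonist_onset) else 0L
    onsets <- sort(stats::runif(n_ev, 0, antagonist_onset))
    x <- .add_events(x, floor(onsets * cfg$sampling_rate) + 1L, tpl,
                     rep(-mini_amp, n_ev))
    if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
    list(x = x, onsets = onsets)
  })
  list(trace = ephys_trace(out$x, cfg$sampling_rate, "pA", channel = "Im"),
       truth = list(tonic_shift = tonic_shift,
                    antagonist_onset = antagonist_onset,
                    settle_duration = settle_duration,
                    mini_onsets = out$onsets))
}

#' Ground truth for a synthetic EEG recording
#'
#' @param spike_times Planted epileptiform spike times (s).
#' @param spike_amplitudes Spike peak magnitudes (microvolt); recycled.
#' @param artifact_intervals Two-column matrix or list of `c(start, end)`
#'   pairs (s); every interval must exceed 200 ms.
#' @param band_mix Relative power targets for the delta/theta/alpha/beta
#'   bands (length 4); normalized with a warning if it does not sum to 1.
#' @return An object of class `"eeg_ground_truth"`.
#' @export
eeg_ground_truth <- function(spike_times = numeric(), spike_amplitudes = numeric(),
                             artifact_intervals = NULL,
                             band_mix = c(3, 5, 4, 17) / 29) {
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) > 0) {
    spike_amplitudes <- rep_len(as.numeric(spike_amplitudes), length(spike_times))
  }
  if (!is.null(artifact_intervals)) {
    if (is.list(artifact_intervals)) {
      artifact_intervals <- do.call(rbind, artifact_intervals)
    }
    artifact_intervals <- matrix(as.numeric(artifact_intervals), ncol = 2)
    if (any(artifact_intervals[, 2] - artifact_intervals[, 1] <= 0.2)) {
      stop("artifact intervals must exceed 200 ms")
    }
    for (k in seq_along(spike_times)) {
      inside <- spike_times[k] >= artifact_intervals[, 1] &
        spike_times[k] <= artifact_intervals[, 2]
      if (any(inside)) stop("planted spikes must lie outside artifact intervals")
    }
  } else {
    artifact_intervals <- matrix(numeric(), ncol = 2)
  }
  if (length(band_mix) != 4 || any(band_mix < 0) || sum(band_mix) <= 0) {
    stop("'band_mix' must be 4 non-negative weights")
  }
  if (abs(sum(band_mix) - 1) > 1e-8) {
    warning("band_mix does not sum to 1; normalizing")
    band_mix <- band_mix / sum(band_mix)
  }
  structure(list(spike_times = spike_times,
                 spike_amplitudes = spike_amplitudes,
                 artifact_intervals = artifact_intervals,
                 band_mix = band_mix),
            class = "eeg_ground_truth")
}

# biphasic spike template: sharp negative lobe then smaller positive rebound,
# total width ~60 ms, unit negative peak
.eeg_spike_template <- function(sampling_rate, neg_ms = 25, pos_ms = 35,
                                pos_frac = 0.35) {
  n1 <- max(2L, round(neg_ms / 1000 * sampling_rate))
  n2 <- max(2L, round(pos_ms / 1000 * sampling_rate))
  lobe1 <- -sin(pi * seq(0, 1, length.out = n1))
  lobe2 <- pos_frac * sin(pi * seq(0, 1, length.out = n2))
  c(lobe1, lobe2)
}

#' Simulate an EEG recording with planted spikes and slow artifacts
#'
#' Background is synthesized in the frequency domain with a piecewise-flat
#' power spectrum over the 1-30 Hz analysis range matching `gt$band_mix`,
#' plus a low-level 1/f tail outside that range, scaled to `cfg$noise_sd`
#' microvolts overall.  Biphasic spike transients (< 200 ms wide) are
#' inserted at `gt$spike_times`; slow raised-cosine artifacts spanning
#' `gt$artifact_intervals` (> 200 ms) are added on top.
#'
#' @param cfg A [synth_config()]; `sampling_rate` must be at least 60 Hz.
#' @param gt An [eeg_ground_truth()].
#' @param artifact_amplitude Peak artifact amplitude (microvolt; default
#'   10x the background SD).
#' @return List with `recording` (an [eeg_recording()], artifact intervals
#'   annotated) and `ground_truth` (unchanged `gt`).
#' @export
gen_eeg <- function(cfg, gt, artifact_amplitude = 10 * cfg$noise_sd) {
  stopifnot(inherits(cfg, "synth_config"), inherits(gt, "eeg_ground_truth"))
  if (cfg$sampling_rate < 60) stop("sampling_rate must cover the beta band (>= 60 Hz)")
  if (length(gt$spike_times) > 0 &&
      (min(gt$spike_times) < 0 || max(gt$spike_times) > cfg$duration)) {
    stop("spike times must lie within [0, duration]")
  }
  n <- round(cfg$duration * cfg$sampling_rate)
  freq <- seq(0, cfg$sampling_rate / 2, length.out = floor(n / 2) + 1)
  bands <- .default_bands()
  shape <- numeric(length(freq))
  for (b in seq_len(4)) {
    sel <- freq >= bands$low[b] & freq < bands$high[b]
    if (any(sel)) {
      shape[sel] <- gt$band_mix[b] / (bands$high[b] - bands$low[b])
    }
  }
  # gentle spectral tail outside the analysis range, well below the in-band
  # level: flat-ish below 1 Hz, steep (1/f^2) rolloff above 30 Hz as in
  # hardware-filtered EEG
  out_band <- shape == 0 & freq > 0.1
  shape[out_band] <- 0.02 * min(gt$band_mix / (bands$high - bands$low)) /
    pmax((freq[out_band] / 30)^2, 1)
  # random-phase spectral synthesis: per-bin amplitude fixed by the target
  # spectrum, phases uniform.  The realized spectral content then matches
  # band_mix exactly at the native frequency resolution, which is what a
  # ground-truth generator owes its consumers; a surrogate of this kind is
  # indistinguishable from filtered Gaussian noise for the detectors here.
  x <- withr::with_seed(.substream(cfg$seed, 53L), {
    amp <- sqrt(shape)
    theta <- stats::runif(length(freq), 0, 2 * pi)
    spec <- complex(modulus = amp, argument = theta)
    spec[1] <- 0
    if (n %% 2 == 0) spec[length(freq)] <- amp[length(freq)] * cos(theta[length(freq)])
    full <- c(spec, Conj(rev(spec[2:(length(freq) - (n %% 2 == 0))])))
    Re(stats::fft(full, inverse = TRUE)) / sqrt(n)
  })
  if (stats::sd(x) > 0) x <- x * (cfg$noise_sd / stats::sd(x))
  tpl <- .eeg_spike_template(cfg$sampling_rate)
  # spike time = negative extremum; template negative peak sits at neg lobe centre
  i_peak_off <- which.min(tpl) - 1L
  if (length(gt$spike_times) > 0) {
    starts <- floor(gt$spike_times * cfg$sampling_rate) + 1L - i_peak_off
    keep <- starts >= 1
    x <- .add_events(x, starts[keep], tpl, gt$spike_amplitudes[keep])
  }
  if (nrow(gt$artifact_intervals) > 0) {
    for (k in seq_len(nrow(gt$artifact_intervals))) {
      i1 <- max(1L, floor(gt$artifact_intervals[k, 1] * cfg$sampling_rate) + 1L)
      i2 <- min(n, floor(gt$artifact_intervals[k, 2] * cfg$sampling_rate))
      m <- i2 - i1 + 1L
      # flat-topped tapered cosine: the excursion stays near full amplitude
      # for most of the planted interval, so its supra-threshold duration
      # tracks the interval length
      u <- seq(0, 1, length.out = m)
      a <- 0.25
      w <- rep(1, m)
      lo <- u < a / 2
      hi <- u > 1 - a / 2
      w[lo] <- 0.5 * (1 - cos(2 * pi * u[lo] / a))
      w[hi] <- 0.5 * (1 - cos(2 * pi * (1 - u[hi]) / a))
      x[i1:i2] <- x[i1:i2] - artifact_amplitude * w
    }
  }
  ann <- if (nrow(gt$artifact_intervals) > 0) {
    data.frame(start_s = gt$artifact_intervals[, 1],
               end_s = gt$artifact_intervals[, 2],
               label = "artifact")
  } else {
    data.frame(start_s = numeric(), end_s = numeric(), label = character())
  }
  rec <- eeg_recording(x, cfg$sampling_rate, annotations = ann)
  list(recording = rec, ground_truth = gt)
}
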