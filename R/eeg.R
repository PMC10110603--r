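#' EEG recording container
#'
#' A single-channel EEG signal in microvolts with labeled annotation
#' intervals (e.g. a non-REM baseline stretch for the spike threshold, and
#' artifact intervals excluded from spectral epochs).
#'
#' @param signal Numeric vector, microvolts.
#' @param sampling_rate Hz (> 60 so the beta band is covered; recordings
#'   in the supported protocols are digitized at 2000 Hz).
#' @param annotations data.frame with columns `start_s`, `end_s`, `label`,
#'   or `NULL`.
#' @return An object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(signal, sampling_rate, annotations = NULL) {
  if (sampling_rate <= 60) stop("'sampling_rate' must exceed 60 Hz")
  dur <- length(signal) / sampling_rate
  if (is.null(annotations)) {
    annotations <- data.frame(start_s = numeric(), end_s = numeric(),
                              label = character())
  }
  stopifnot(all(c("start_s", "end_s", "label") %in% names(annotations)))
  if (nrow(annotations) > 0 &&
      (any(annotations$start_s < 0) || any(annotations$end_s > dur + 1e-9))) {
    stop("annotation intervals must lie within the recording")
  }
  structure(list(signal = as.numeric(signal),
                 sampling_rate = sampling_rate,
                 annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples @ %g Hz (%.1f s), %d annotation(s)\n",
              length(x$signal), x$sampling_rate,
              length(x$signal) / x$sampling_rate, nrow(x$annotations)))
  invisible(x)
}

#' Epileptiform spike detection parameters
#'
#' Defaults follow the rule set used throughout: threshold at four times
#' the SD of the non-REM baseline, waveforms longer than 200 ms rejected as
#' artifacts, and at least three consecutive spikes at intervals of at most
#' 200 ms forming a discharge.
#'
#' @param threshold_multiplier Threshold in baseline-SD units (default 4).
#' @param baseline_interval `c(start, end)` seconds of the non-REM
#'   reference stretch, or `NULL` to use the annotation labeled
#'   `baseline_label`.
#' @param baseline_label Annotation label naming the baseline (default
#'   `"nonrem"`).
#' @param max_waveform_duration_ms Reject supra-threshold waveforms longer
#'   than this (ms, default 200).
#' @param min_spikes_per_discharge Minimum spikes per discharge (default 3).
#' @param max_within_discharge_interval_ms Maximum inter-spike interval
#'   within a discharge (ms, default 200).
#' @param merge_gap_ms Supra-threshold excursions separated by less than
#'   this gap are treated as one waveform (ms, default 25), so a spike's
#'   rebound lobe is not counted as a second spike.
#' @param min_waveform_duration_ms Discard excursions shorter than this
#'   (ms, default 4): an epileptiform spike lasts tens of milliseconds,
#'   while sub-millisecond threshold blips are noise.
#' @return An object of class `"spike_detection_params"`.
#' @export
spike_detection_params <- function(threshold_multiplier = 4,
                                   baseline_interval = NULL,
                                   baseline_label = "nonrem",
                                   max_waveform_duration_ms = 200,
                                   min_spikes_per_discharge = 3,
                                   max_within_discharge_interval_ms = 200,
                                   merge_gap_ms = 25,
                                   min_waveform_duration_ms = 4) {
  stopifnot(threshold_multiplier > 0, max_waveform_duration_ms > 0,
            min_spikes_per_discharge > 0,
            max_within_discharge_interval_ms > 0, merge_gap_ms >= 0,
            min_waveform_duration_ms >= 0)
  structure(list(threshold_multiplier = threshold_multiplier,
                 baseline_interval = baseline_interval,
                 baseline_label = baseline_label,
                 max_waveform_duration_ms = max_waveform_duration_ms,
                 min_spikes_per_discharge = min_spikes_per_discharge,
                 max_within_discharge_interval_ms = max_within_discharge_interval_ms,
                 merge_gap_ms = merge_gap_ms,
                 min_waveform_duration_ms = min_waveform_duration_ms),
            class = "spike_detection_params")
}

#' Detect epileptiform EEG spikes by amplitude threshold
#'
#' The threshold is `threshold_multiplier` times the SD of the signal over
#' the non-REM baseline interval.  A candidate is a contiguous excursion of
#' the rectified signal above threshold (either polarity; nearby excursions
#' separated by less than `merge_gap_ms` are fused).  Its duration is the
#' time between threshold crossings; candidates longer than
#' `max_waveform_duration_ms` are rejected as artifacts.  The spike time is
#' the time of the rectified extremum.
#'
#' @param rec An [eeg_recording()].
#' @param params A [spike_detection_params()].  The baseline interval must
#'   be given there or annotated on the recording, and must be at least
#'   10 s long.
#' @return An object of class `"eeg_spikes"`: data.frame with columns
#'   `time_s`, `amplitude_uV` (signed extremum), `duration_ms`; attributes
#'   `threshold_uV`, `baseline_sd`, `n_rejected_artifacts`.
#' @export
detect_spikes <- function(rec, params = spike_detection_params()) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(params, "spike_detection_params"))
  fs <- rec$sampling_rate
  bl <- params$baseline_interval
  if (is.null(bl)) {
    hit <- rec$annotations$label == params$baseline_label
    if (!any(hit)) {
      stop("no baseline interval: supply params$baseline_interval or annotate '",
           params$baseline_label, "'")
    }
    bl <- c(rec$annotations$start_s[hit][1], rec$annotations$end_s[hit][1])
  }
  if (diff(bl) < 10) stop("baseline interval must be at least 10 s")
  i1 <- max(1L, floor(bl[1] * fs) + 1L)
  i2 <- min(length(rec$signal), floor(bl[2] * fs))
  baseline_sd <- stats::sd(rec$signal[i1:i2])
  thr <- params$threshold_multiplier * baseline_sd
  empty <- data.frame(time_s = numeric(), amplitude_uV = numeric(),
                      duration_ms = numeric())
  if (!is.finite(thr) || thr <= 0) {
    return(structure(empty, class = c("eeg_spikes", "data.frame"),
                     threshold_uV = thr, baseline_sd = baseline_sd,
                     n_rejected_artifacts = 0L))
  }
  above <- abs(rec$signal) > thr
  if (!any(above)) {
    return(structure(empty, class = c("eeg_spikes", "data.frame"),
                     threshold_uV = thr, baseline_sd = baseline_sd,
                     n_rejected_artifacts = 0L))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # fuse excursions separated by less than merge_gap_ms
  gap <- round(params$merge_gap_ms / 1000 * fs)
  if (nrow(runs) > 1 && gap > 0) {
    fused <- runs[1, , drop = FALSE]
    for (k in 2:nrow(runs)) {
      if (runs[k, 1] - fused[nrow(fused), 2] <= gap) {
        fused[nrow(fused), 2] <- runs[k, 2]
      } else {
        fused <- rbind(fused, runs[k, ])
      }
    }
    runs <- fused
  }
  dur_ms <- (runs[, 2] - runs[, 1] + 1L) / fs * 1000
  too_short <- dur_ms < params$min_waveform_duration_ms
  runs <- runs[!too_short, , drop = FALSE]
  dur_ms <- dur_ms[!too_short]
  ok <- dur_ms <= params$max_waveform_duration_ms
  n_rej <- sum(!ok)
  runs <- runs[ok, , drop = FALSE]
  dur_ms <- dur_ms[ok]
  if (nrow(runs) == 0) {
    return(structure(empty, class = c("eeg_spikes", "data.frame"),
                     threshold_uV = thr, baseline_sd = baseline_sd,
                     n_rejected_artifacts = n_rej))
  }
  pk <- vapply(seq_len(nrow(runs)), function(k) {
    seg <- rec$signal[runs[k, 1]:runs[k, 2]]
    j <- which.max(abs(seg))
    c(runs[k, 1] + j - 1L, seg[j])
  }, numeric(2))
  out <- data.frame(time_s = (pk[1, ] - 1L) / fs,
                    amplitude_uV = pk[2, ],
                    duration_ms = dur_ms)
  structure(out[order(out$time_s), ],
            class = c("eeg_spikes", "data.frame"),
            threshold_uV = thr, baseline_sd = baseline_sd,
            n_rejected_artifacts = n_rej)
}

#' @export
print.eeg_spikes <- function(x, ...) {
  cat(sprintf("<eeg_spikes> %d spikes (threshold %.2f uV, %d artifact(s) rejected)\n",
              nrow(x), attr(x, "threshold_uV"), attr(x, "n_rejected_artifacts")))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}

#' Group spikes into epileptiform discharges
#'
#' Maximal runs of spikes whose consecutive inter-spike intervals are all
#' at most `max_within_discharge_interval_ms`; runs with at least
#' `min_spikes_per_discharge` spikes are counted as discharges, shorter
#' runs are discarded.
#'
#' @param spike_times Sorted spike times, s (or an [detect_spikes()]
#'   result).
#' @param params A [spike_detection_params()].
#' @return data.frame of class `"discharges"`: `onset_s`, `offset_s`,
#'   `n_spikes`, one row per discharge; member spike times in attribute
#'   `members` (list).
#' @export
group_discharges <- function(spike_times, params = spike_detection_params()) {
  if (inherits(spike_times, "eeg_spikes")) spike_times <- spike_times$time_s
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) stop("'spike_times' must be sorted ascending")
  empty <- structure(data.frame(onset_s = numeric(), offset_s = numeric(),
                                n_spikes = integer()),
                     class = c("discharges", "data.frame"),
                     members = list())
  n <- length(spike_times)
  if (n == 0) return(empty)
  max_isi <- params$max_within_discharge_interval_ms / 1000
  brk <- c(0, which(diff(spike_times) > max_isi), n)
  members <- list()
  rows <- NULL
  for (k in seq_len(length(brk) - 1)) {
    idx <- (brk[k] + 1):brk[k + 1]
    if (length(idx) >= params$min_spikes_per_discharge) {
      members[[length(members) + 1L]] <- spike_times[idx]
      rows <- rbind(rows, c(spike_times[idx[1]],
                            spike_times[idx[length(idx)]], length(idx)))
    }
  }
  if (is.null(rows)) return(empty)
  out <- data.frame(onset_s = rows[, 1], offset_s = rows[, 2],
                    n_spikes = as.integer(rows[, 3]))
  structure(out, class = c("discharges", "data.frame"), members = members)
}

#' @export
print.discharges <- function(x, ...) {
  cat(sprintf("<discharges> %d epileptiform discharge(s)\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' Discharge rate
#'
#' Discharge count normalized to rate per hour; count and analyzed duration
#' are reported alongside so alternative normalizations can be recomputed.
#'
#' @param discharges A [group_discharges()] result (or a count).
#' @param analyzed_duration_s Analyzed duration, s (> 0).
#' @return List: `n_discharges`, `analyzed_hours`, `rate_per_hour`.
#' @export
discharge_rate <- function(discharges, analyzed_duration_s) {
  if (analyzed_duration_s <= 0) stop("'analyzed_duration_s' must be > 0")
  n <- if (is.data.frame(discharges)) nrow(discharges) else as.integer(discharges)
  hours <- analyzed_duration_s / 3600
  list(n_discharges = n, analyzed_hours = hours, rate_per_hour = n / hours)
}

.default_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta"),
             low = c(1, 4, 9, 13), high = c(4, 9, 13, 30))
}

#' Welch power spectral density
#'
#' Segment-averaged periodogram: Hann-tapered segments of `window_s`
#' seconds with `overlap` fractional overlap, mean-detrended per segment,
#' one-sided density normalization.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param window_s Segment length, s (default 2).
#' @param overlap Fractional overlap (default 0.5).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  nw <- round(window_s * fs)
  if (nw > length(x)) stop("signal shorter than one Welch segment")
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / nw)
  U <- sum(w^2)
  acc <- numeric(nw)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  P <- acc / (length(starts) * U * fs)
  nf <- floor(nw / 2) + 1L
  psd <- P[seq_len(nf)]
  # one-sided: double everything except DC (and Nyquist when present)
  dbl <- 2:(nf - (nw %% 2 == 0))
  psd[dbl] <- 2 * psd[dbl]
  list(freq = (seq_len(nf) - 1L) * fs / nw, psd = psd)
}

#' Relative EEG band powers over awake epochs
#'
#' Per-epoch Welch power spectral density; band power is the integral of
#' the density over each band (half-open intervals `[low, high)`), and
#' relative power is each band divided by the summed power of the four
#' bands, so the four relative powers sum to one per epoch.  The summary is
#' the mean over epochs.  Epochs overlapping an annotated artifact are
#' rejected with a warning.
#'
#' @param rec An [eeg_recording()].
#' @param epochs Two-column matrix or list of `c(start, end)` pairs (s);
#'   conventionally ten 9-s artifact-free awake epochs.
#' @param bands data.frame with `band`, `low`, `high` (Hz); default
#'   delta 1-4, theta 4-9, alpha 9-13, beta 13-30.
#' @param window_s,overlap Welch parameters (see [welch_psd()]).
#' @return An object of class `"band_power_summary"`: list with
#'   `relative` (named mean relative powers), `absolute` (mean band powers,
#'   signal-units^2), `per_epoch_relative` (epochs x bands matrix),
#'   `n_epochs`, `epoch_duration_s`, `bands`.
#' @export
relative_band_powers <- function(rec, epochs, bands = .default_bands(),
                                 window_s = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.list(epochs)) epochs <- do.call(rbind, epochs)
  epochs <- matrix(as.numeric(epochs), ncol = 2)
  if (nrow(epochs) == 0) stop("at least one epoch is required")
  fs <- rec$sampling_rate
  art <- rec$annotations[rec$annotations$label == "artifact", , drop = FALSE]
  rel <- NULL
  abs_p <- NULL
  used <- 0L
  for (k in seq_len(nrow(epochs))) {
    ep <- epochs[k, ]
    if (nrow(art) > 0 &&
        any(art$start_s < ep[2] & art$end_s > ep[1])) {
      warning(sprintf("epoch %d [%.1f, %.1f] s overlaps an artifact; rejected",
                      k, ep[1], ep[2]))
      next
    }
    i1 <- max(1L, floor(ep[1] * fs) + 1L)
    i2 <- min(length(rec$signal), floor(ep[2] * fs))
    sp <- welch_psd(rec$signal[i1:i2], fs, window_s, overlap)
    df <- sp$freq[2] - sp$freq[1]
    bp <- vapply(seq_len(nrow(bands)), function(b) {
      sel <- sp$freq >= bands$low[b] & sp$freq < bands$high[b]
      sum(sp$psd[sel]) * df
    }, numeric(1))
    rel <- rbind(rel, bp / sum(bp))
    abs_p <- rbind(abs_p, bp)
    used <- used + 1L
  }
  if (used == 0L) stop("all epochs were rejected for artifact overlap")
  colnames(rel) <- colnames(abs_p) <- bands$band
  structure(list(relative = colMeans(rel),
                 absolute = colMeans(abs_p),
                 per_epoch_relative = rel,
                 n_epochs = used,
                 epoch_duration_s = mean(epochs[, 2] - epochs[, 1]),
                 bands = bands),
            class = "band_power_summary")
}

#' @export
print.band_power_summary <- function(x, ...) {
  cat(sprintf("relative band powers over %d epoch(s) of %.1f s:\n",
              x$n_epochs, x$epoch_duration_s))
  print(round(x$relative, 4))
  invisible(x)
}
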