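#' Detect miniature postsynaptic currents
#'
#' Automated threshold detection: the polarity-aligned, baseline-subtracted
#' signal must exceed `threshold_multiplier` times a robust noise SD
#' (median absolute deviation, which events do not inflate the way a naive
#' SD would).  The slow baseline is removed with a long running median.
#' Candidate peaks closer than the refractory minimum are merged (larger
#' peak kept).  Each retained event is characterized with
#' [characterize_event()].
#'
#' @param trace An [ephys_trace()] current trace, at least 10 s long.
#' @param polarity `"inward"` (negative events, default) or `"outward"`.
#' @param threshold_multiplier Detection threshold in units of noise SD
#'   (default 3.5).
#' @param refractory_ms Minimum separation between event peaks (ms,
#'   default 5); closer candidates are merged.
#' @param baseline_s Running-median baseline window (s, default 0.5).
#' @param smooth_ms Moving-average width of the detection signal (ms,
#'   default 0.5); suppresses single-sample noise crossings while leaving
#'   millisecond-scale event rise times intact.
#' @param min_duration_ms Minimum supra-threshold duration of a candidate
#'   (ms, default 1); white noise almost never stays above threshold this
#'   long, a synaptic event does.
#' @param characterize Fit per-event kinetics (default TRUE).
#' @return An object of class `"mini_events"`: data.frame with columns
#'   `onset_s`, `peak_s`, `amplitude_pA`, `rise_ms`, `decay_ms`, `flagged`
#'   (kinetic fit failed), sorted by onset.  Attributes: `duration_s`,
#'   `noise_sd`, `threshold`, `polarity`.
#' @export
detect_minis <- function(trace, polarity = c("inward", "outward"),
                         threshold_multiplier = 3.5, refractory_ms = 5,
                         baseline_s = 0.5, smooth_ms = 0.5,
                         min_duration_ms = 1, characterize = TRUE) {
  stopifnot(inherits(trace, "ephys_trace"))
  polarity <- match.arg(polarity)
  if (trace_duration(trace) < 10) {
    stop("trace must be at least 10 s long for stable noise estimation")
  }
  x <- trace$samples
  # saturation check: many samples pinned at an extreme value far from the
  # typical level (a flat baseline equals its own extreme and is fine)
  rng <- range(x)
  med <- stats::median(x)
  scale <- max(stats::mad(x), 1e-12)
  for (rail in rng) {
    frac <- mean(x == rail)
    if (frac > 0.005 && abs(rail - med) > 5 * scale) {
      stop(sprintf(paste0("trace appears saturated/clipped: %.1f%% of ",
                          "samples sit pinned at %g %s"),
                   100 * frac, rail, trace$units))
    }
  }
  fs <- trace$sampling_rate
  k <- min(length(x), round(baseline_s * fs))
  if (k %% 2 == 0) k <- k + 1L
  baseline <- stats::runmed(x, k, endrule = "median")
  y <- (x - baseline) * if (polarity == "inward") -1 else 1
  ks <- max(1L, round(smooth_ms / 1000 * fs))
  if (ks > 1) {
    y <- as.numeric(stats::filter(y, rep(1 / ks, ks), sides = 2))
    y[is.na(y)] <- 0
  }
  noise_sd <- stats::mad(y)
  if (!is.finite(noise_sd) || noise_sd == 0) {
    # noiseless traces: fall back to any positive scale so the threshold
    # is defined; detection then keys on the events themselves
    noise_sd <- max(stats::sd(y) * 1e-6, .Machine$double.eps)
  }
  thr <- threshold_multiplier * noise_sd
  above <- y > thr
  if (!any(above)) {
    ev <- data.frame(onset_s = numeric(), peak_s = numeric(),
                     amplitude_pA = numeric(), rise_ms = numeric(),
                     decay_ms = numeric(), flagged = logical())
    return(.as_mini_events(ev, trace, noise_sd, thr, polarity))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # fuse runs separated by less than the refractory minimum: a decaying
  # tail hovering at threshold re-crosses repeatedly but is one event
  gap <- round(refractory_ms / 1000 * fs)
  if (nrow(runs) > 1 && gap > 0) {
    fused <- runs[1, , drop = FALSE]
    for (j in 2:nrow(runs)) {
      if (runs[j, 1] - fused[nrow(fused), 2] <= gap) {
        fused[nrow(fused), 2] <- runs[j, 2]
      } else {
        fused <- rbind(fused, runs[j, ])
      }
    }
    runs <- fused
  }
  min_len <- max(1L, round(min_duration_ms / 1000 * fs))
  runs <- runs[runs[, 2] - runs[, 1] + 1L >= min_len, , drop = FALSE]
  if (nrow(runs) == 0) {
    ev <- data.frame(onset_s = numeric(), peak_s = numeric(),
                     amplitude_pA = numeric(), rise_ms = numeric(),
                     decay_ms = numeric(), flagged = logical())
    return(.as_mini_events(ev, trace, noise_sd, thr, polarity))
  }
  # split runs holding several superimposed events: distinct smoothed
  # peaks separated by >= the refractory with a pronounced valley between
  parts <- lapply(seq_len(nrow(runs)), function(k) {
    seg <- y[runs[k, 1]:runs[k, 2]]
    sp <- .split_peaks(seg, thr, min_sep = gap)
    cbind(onset = runs[k, 1] + sp$onsets - 1L,
          peak = runs[k, 1] + sp$peaks - 1L,
          split = c(0L, rep(1L, length(sp$peaks) - 1L)))
  })
  tab <- do.call(rbind, parts)
  onset_idx <- tab[, "onset"]
  peak_idx <- tab[, "peak"]
  is_split <- tab[, "split"] == 1L
  onset_s <- trace$t0 + (onset_idx - 1L) / fs
  peak_s <- trace$t0 + (peak_idx - 1L) / fs
  if (characterize) {
    # kinetics need a clean tail: skip the fit when the next event starts
    # within 20 ms (the event still counts toward frequency)
    clean_tail_s <- 0.020
    gap_next <- c(diff(onset_s), Inf)
    ch <- lapply(seq_along(onset_s), function(j) {
      # analysis window stops at the next event so a neighbor cannot
      # contaminate the peak or the decay fit
      w_ms <- min(50, max(2, gap_next[j] * 1000 - 0.5))
      # a split event sits on its predecessor's decaying tail: take its
      # baseline right at the valley, not 5 ms back into the predecessor
      characterize_event(trace, onset_s[j], polarity = polarity,
                         window_ms = w_ms,
                         baseline_ms = if (is_split[j]) 1 else 5,
                         kinetics = gap_next[j] >= clean_tail_s)
    })
    ev <- do.call(rbind, ch)
    ev$onset_s <- onset_s
    ev$peak_s <- peak_s
  } else {
    ev <- data.frame(onset_s = onset_s, peak_s = peak_s,
                     amplitude_pA = y[peak_idx], rise_ms = NA_real_,
                     decay_ms = NA_real_, flagged = FALSE)
  }
  ev <- ev[order(ev$onset_s),
           c("onset_s", "peak_s", "amplitude_pA", "rise_ms", "decay_ms",
             "flagged")]
  rownames(ev) <- NULL
  .as_mini_events(ev, trace, noise_sd, thr, polarity)
}

.as_mini_events <- function(ev, trace, noise_sd, thr, polarity) {
  structure(ev, class = c("mini_events", "data.frame"),
            duration_s = trace_duration(trace), noise_sd = noise_sd,
            threshold = thr, polarity = polarity)
}

#' @export
print.mini_events <- function(x, ...) {
  cat(sprintf("<mini_events> %d events in %.1f s (%.2f /s), threshold %.2f pA\n",
              nrow(x), attr(x, "duration_s"),
              nrow(x) / attr(x, "duration_s"), attr(x, "threshold")))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Characterize a single miniature event
#'
#' Measures the quantities reported per event: peak amplitude relative to a
#' local pre-onset baseline, 10-90% rise time on the rising limb (linear
#' interpolation between samples), and the decay time as a monoexponential
#' time constant fitted on the falling limb.  The peak is located on a
#' lightly smoothed copy of the signal and the amplitude is the mean of
#' the raw signal over a short window around that peak, which removes the
#' upward selection bias a raw max-over-window estimate suffers under
#' noise.  A fit that does not converge, or a waveform with no decay
#' (step-like), flags the event; flagged events are excluded from kinetic
#' averages but still count toward frequency.
#'
#' @param trace An [ephys_trace()].
#' @param onset Event onset time, s.
#' @param polarity `"inward"` or `"outward"`.
#' @param baseline_ms Local baseline window ending at onset (ms).
#' @param window_ms Analysis window after onset (ms).
#' @param smooth_ms Moving-average width for peak location and kinetic
#'   measurements (ms, default 0.5).
#' @param peak_avg_ms Half-width of the raw-signal average defining the
#'   amplitude (ms, default 0.5).
#' @param fit_start_frac The decay fit starts where the falling limb first
#'   drops below this fraction of the peak (default 0.8), past the residual
#'   curvature of the rising component just after the peak.
#' @param kinetics Fit rise/decay kinetics (default TRUE); when FALSE the
#'   event is measured for amplitude only and flagged.
#' @return One-row data.frame: `onset_s`, `peak_s`, `amplitude_pA`
#'   (positive magnitude), `rise_ms`, `decay_ms`, `flagged`.
#' @export
characterize_event <- function(trace, onset, polarity = c("inward", "outward"),
                               baseline_ms = 5, window_ms = 50,
                               smooth_ms = 0.5, peak_avg_ms = 0.5,
                               fit_start_frac = 0.8, kinetics = TRUE) {
  stopifnot(inherits(trace, "ephys_trace"))
  polarity <- match.arg(polarity)
  fs <- trace$sampling_rate
  sgn <- if (polarity == "inward") -1 else 1
  i_on <- .time_to_index(trace, onset)
  i_b1 <- max(1L, i_on - round(baseline_ms / 1000 * fs))
  i_end <- min(length(trace$samples), i_on + round(window_ms / 1000 * fs))
  if (i_end <= i_on + 2L) stop("event window extends beyond the trace")
  raw <- (trace$samples[i_b1:i_end] -
            mean(trace$samples[i_b1:max(i_b1, i_on - 1L)])) * sgn
  ks <- max(1L, round(smooth_ms / 1000 * fs))
  ys <- if (ks > 1) {
    v <- as.numeric(stats::filter(raw, rep(1 / ks, ks), sides = 2))
    v[is.na(v)] <- raw[is.na(v)]
    v
  } else raw
  o <- i_on - i_b1 + 1L          # onset position within the local window
  k_pk <- o - 1L + which.max(ys[o:length(ys)])
  ka <- max(1L, round(peak_avg_ms / 1000 * fs))
  amp <- mean(raw[max(1L, k_pk - ka):min(length(raw), k_pk + ka)])
  flagged <- FALSE
  # 10-90% rise time with sub-sample interpolation on the smoothed limb
  rise_ms <- NA_real_
  if (kinetics && k_pk > o) {
    limb <- ys[o:k_pk]
    t10 <- .cross_time(limb, 0.1 * amp)
    t90 <- .cross_time(limb, 0.9 * amp)
    if (is.finite(t10) && is.finite(t90) && t90 >= t10) {
      rise_ms <- (t90 - t10) / fs * 1000
    }
  }
  if (kinetics && !is.finite(rise_ms)) flagged <- TRUE
  # monoexponential decay fit on the falling limb; start below
  # fit_start_frac * peak so the residual rising component has died away
  decay_ms <- NA_real_
  if (kinetics) {
    post <- ys[k_pk:length(ys)]
    j0 <- which(post <= fit_start_frac * amp)
    k_fit <- if (length(j0) > 0) k_pk + j0[1] - 1L else k_pk
    tail_y <- ys[k_fit:length(ys)]
    tt <- (seq_along(tail_y) - 1L) / fs * 1000
    cross <- which(tail_y <= amp / exp(1))
    if (length(cross) == 0 || length(tail_y) < 5) {
      flagged <- TRUE  # no decay within the window: step-like or truncated
    } else {
      tau0 <- tt[cross[1]]
      fit <- tryCatch(
        minpack.lm::nlsLM(tail_y ~ A * exp(-tt / tau),
                          start = list(A = tail_y[1],
                                       tau = max(tau0, 1 / fs * 1000)),
                          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (is.null(fit)) {
        flagged <- TRUE
      } else {
        tau <- unname(stats::coef(fit)["tau"])
        if (!is.finite(tau) || tau <= 0 || tau > 10 * max(tt)) {
          flagged <- TRUE
        } else {
          decay_ms <- tau
        }
      }
    }
  } else {
    flagged <- TRUE
  }
  data.frame(onset_s = onset,
             peak_s = onset + (k_pk - o) / fs,
             amplitude_pA = amp, rise_ms = rise_ms, decay_ms = decay_ms,
             flagged = flagged)
}

# split a supra-threshold run into distinct events: local maxima of the
# (smoothed) detection signal separated by >= min_sep samples, each rising
# at least a full threshold height above the valley between them (noise
# bumps riding a decaying tail lack that prominence); onsets of secondary
# events sit at the valley minimum
.split_peaks <- function(yseg, thr, min_sep) {
  n <- length(yseg)
  loc <- if (n < 3) integer() else
    which(yseg > thr &
            yseg >= c(-Inf, yseg[-n]) & yseg > c(yseg[-1], Inf))
  if (length(loc) == 0) loc <- which.max(yseg)
  repeat {
    if (length(loc) == 1) break
    merged <- FALSE
    for (j in seq_len(length(loc) - 1)) {
      p <- loc[j]; q <- loc[j + 1]
      valley <- min(yseg[p:q])
      if (q - p < min_sep || min(yseg[p], yseg[q]) - valley < thr) {
        loc <- loc[-(if (yseg[p] >= yseg[q]) j + 1 else j)]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  onsets <- c(1L, vapply(seq_along(loc)[-1], function(j) {
    p <- loc[j - 1]; q <- loc[j]
    p + which.min(yseg[p:q]) - 1L
  }, integer(1)))
  list(peaks = loc, onsets = onsets)
}

# first upward crossing time (in samples, 0-based, interpolated) of level
.cross_time <- function(y, level) {
  idx <- which(y >= level)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  if (i == 1) return(0)
  frac <- (level - y[i - 1]) / (y[i] - y[i - 1])
  (i - 2) + frac
}

#' Summarize detected miniature events
#'
#' Event frequency in the requested unit and arithmetic means of the
#' per-event measures over non-flagged events.
#'
#' @param events A [detect_minis()] result (or compatible data.frame).
#' @param duration Analyzed duration, s.  Defaults to the duration recorded
#'   on the event set.
#' @param frequency_unit `"per_s"` (mIPSC convention) or `"per_min"`
#'   (mEPSC convention).
#' @return An object of class `"mini_summary"`: list with `n_events`,
#'   `frequency`, `frequency_unit`, `mean_amplitude_pA`, `mean_rise_ms`,
#'   `mean_decay_ms`, `n_flagged`, `duration_s`.  Kinetic means are `NA`
#'   when there are no usable events.
#' @export
summarize_minis <- function(events, duration = attr(events, "duration_s"),
                            frequency_unit = c("per_s", "per_min")) {
  frequency_unit <- match.arg(frequency_unit)
  if (is.null(duration) || !is.finite(duration) || duration <= 0) {
    stop("'duration' must be a positive number of seconds")
  }
  n <- nrow(events)
  freq <- n / duration * if (frequency_unit == "per_min") 60 else 1
  ok <- if (n > 0) !events$flagged else logical()
  structure(list(
    n_events = n,
    frequency = freq,
    frequency_unit = frequency_unit,
    mean_amplitude_pA = if (any(ok)) mean(events$amplitude_pA[ok]) else NA_real_,
    mean_rise_ms = if (any(ok)) mean(events$rise_ms[ok]) else NA_real_,
    mean_decay_ms = if (any(ok)) mean(events$decay_ms[ok]) else NA_real_,
    n_flagged = sum(!ok),
    duration_s = duration
  ), class = "mini_summary")
}

#' @export
print.mini_summary <- function(x, ...) {
  cat(sprintf("%d events / %.1f s: frequency %.3f %s\n", x$n_events,
              x$duration_s, x$frequency,
              if (x$frequency_unit == "per_s") "/s" else "/min"))
  if (is.finite(x$mean_amplitude_pA)) {
    cat(sprintf("  amplitude %.2f pA, rise %.2f ms, decay %.2f ms (%d flagged)\n",
                x$mean_amplitude_pA, x$mean_rise_ms, x$mean_decay_ms,
                x$n_flagged))
  }
  invisible(x)
}

#' Paired-pulse ratio of evoked responses
#'
#' Ratio of the second to the first evoked peak amplitude.  Each peak is
#' measured against a baseline taken just before its own stimulus, so the
#' residual decay of the first response is subtracted from the second; the
#' stimulus artifact is blanked before peak search.
#'
#' @param trace An [ephys_trace()].
#' @param stim_times Two stimulus times, s (default interval 50 ms).
#' @param artifact_blank_ms Blanking period after each stimulus (ms).
#' @param baseline_ms Baseline window length before each stimulus (ms,
#'   default 2: kept short so the residual decay of the first response is
#'   subtracted at its level just before the second stimulus).
#' @param response_window_ms Peak search window after each stimulus (ms);
#'   the first window is additionally truncated at the second stimulus.
#' @param polarity `"inward"` or `"outward"`.
#' @return Scalar PPR (`peak2 / peak1`), with attribute `peaks` (the two
#'   baseline-subtracted magnitudes, pA).
#' @export
paired_pulse_ratio <- function(trace, stim_times, artifact_blank_ms = 1,
                               baseline_ms = 2, response_window_ms = 45,
                               polarity = c("inward", "outward")) {
  stopifnot(inherits(trace, "ephys_trace"), length(stim_times) == 2)
  polarity <- match.arg(polarity)
  if (diff(stim_times) <= 0) stop("second stimulus must follow the first")
  sgn <- if (polarity == "inward") -1 else 1
  fs <- trace$sampling_rate
  peaks <- numeric(2)
  for (p in 1:2) {
    st <- stim_times[p]
    i_b1 <- .time_to_index(trace, st - baseline_ms / 1000)
    i_b2 <- .time_to_index(trace, st) - 1L
    if (i_b2 < i_b1) stop("baseline window before stimulus ", p, " is empty")
    base <- mean(trace$samples[i_b1:i_b2])
    w_end <- st + response_window_ms / 1000
    if (p == 1) w_end <- min(w_end, stim_times[2])
    i_r1 <- .time_to_index(trace, st + artifact_blank_ms / 1000)
    i_r2 <- .time_to_index(trace, w_end)
    if (i_r2 + 1 > length(trace$samples) + 1 || i_r2 <= i_r1) {
      stop("response window for stimulus ", p, " is outside the trace")
    }
    peaks[p] <- max((trace$samples[i_r1:i_r2] - base) * sgn)
  }
  if (peaks[1] == 0) stop("first peak is zero; paired-pulse ratio undefined")
  out <- peaks[2] / peaks[1]
  attr(out, "peaks") <- peaks
  out
}
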