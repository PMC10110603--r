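#' Event-free baseline segments of a current trace
#'
#' Tonic-current baselines must be measured on stretches devoid of synaptic
#' events.  Around every detected event, the interval
#' `[onset - pre_margin, onset + post_margin]` is excluded; the remaining
#' clean intervals of the search window are accumulated greedily from the
#' window start inward until the required total is reached (the last
#' interval is trimmed to the exact total).  Pooled, not necessarily
#' contiguous.
#'
#' @param trace An [ephys_trace()].
#' @param events A [detect_minis()] result (or data.frame with `onset_s`),
#'   or `NULL` for none.
#' @param window `c(start, end)` search window, s.
#' @param required_total Total clean time required, s (default 3).
#' @param pre_margin_s,post_margin_s Exclusion margins around each event
#'   onset, s (defaults 5 ms before, 50 ms after).
#' @return Matrix with columns `start`, `end` (s); total span equals
#'   `required_total`.  Errors listing the available clean time when the
#'   requirement cannot be met.
#' @export
event_free_segments <- function(trace, events, window,
                                required_total = 3,
                                pre_margin_s = 0.005, post_margin_s = 0.050) {
  stopifnot(inherits(trace, "ephys_trace"), length(window) == 2)
  if (window[2] <= window[1]) stop("'window' must be an increasing (start, end) pair")
  onsets <- if (is.null(events) || nrow(as.data.frame(events)) == 0) {
    numeric()
  } else {
    as.data.frame(events)$onset_s
  }
  excl <- cbind(onsets - pre_margin_s, onsets + post_margin_s)
  clean <- .subtract_intervals(window, excl)
  total_avail <- sum(clean[, 2] - clean[, 1])
  if (total_avail < required_total) {
    stop(sprintf(paste0("cannot accumulate %.2f s of event-free baseline in ",
                        "[%.2f, %.2f] s: only %.2f s available"),
                 required_total, window[1], window[2], total_avail))
  }
  out <- NULL
  need <- required_total
  for (k in seq_len(nrow(clean))) {
    len <- clean[k, 2] - clean[k, 1]
    take <- min(len, need)
    out <- rbind(out, c(clean[k, 1], clean[k, 1] + take))
    need <- need - take
    if (need <= 1e-12) break
  }
  colnames(out) <- c("start", "end")
  out
}

# window minus a set of exclusion intervals -> matrix of clean intervals
.subtract_intervals <- function(window, excl) {
  if (is.null(excl) || nrow(excl) == 0) {
    return(matrix(window, ncol = 2))
  }
  excl <- excl[order(excl[, 1]), , drop = FALSE]
  out <- NULL
  cur <- window[1]
  for (k in seq_len(nrow(excl))) {
    a <- max(window[1], excl[k, 1])
    b <- min(window[2], excl[k, 2])
    if (b <= cur) next
    if (a > cur) out <- rbind(out, c(cur, min(a, window[2])))
    cur <- max(cur, b)
    if (cur >= window[2]) break
  }
  if (cur < window[2]) out <- rbind(out, c(cur, window[2]))
  if (is.null(out)) matrix(numeric(), ncol = 2) else out
}

# mean of trace samples over a set of intervals (pooled)
.mean_over_intervals <- function(trace, intervals) {
  vals <- unlist(lapply(seq_len(nrow(intervals)), function(k) {
    .window_samples(trace, intervals[k, 1], intervals[k, 2])
  }))
  mean(vals)
}

#' Tonic GABA-A current amplitude from an antagonist-induced baseline shift
#'
#' The tonic current is the difference between the mean event-free baseline
#' current during and before antagonist application.  Sign convention:
#' `tonic_amplitude = I_post - I_pre`, positive when the antagonist shifts
#' the baseline outward (toward 0 pA from a negative holding current),
#' i.e. positive values measure the standing inward tonic current that was
#' blocked.
#'
#' @param trace An [ephys_trace()] current trace.
#' @param antagonist_onset Antagonist application time, s.
#' @param settle Wash-in time excluded after the onset, s (default 10).
#' @param events Detected events on the same trace ([detect_minis()]), or
#'   `NULL`.
#' @param required_total Event-free time required per window, s (default 3).
#' @param pre_span Length of the pre-antagonist search window, s; defaults
#'   to everything from the trace start to the onset.
#' @return An object of class `"tonic_result"`: list with `I_pre`, `I_post`
#'   (pA), `tonic_amplitude` (pA), `seconds_used_pre`, `seconds_used_post`,
#'   `segments_pre`, `segments_post`.
#' @export
tonic_amplitude <- function(trace, antagonist_onset, settle = 10,
                            events = NULL, required_total = 3,
                            pre_span = NULL) {
  stopifnot(inherits(trace, "ephys_trace"))
  t_end <- trace$t0 + trace_duration(trace)
  if (antagonist_onset <= trace$t0 || antagonist_onset >= t_end) {
    stop("'antagonist_onset' must lie inside the trace")
  }
  pre_start <- if (is.null(pre_span)) trace$t0 else
    max(trace$t0, antagonist_onset - pre_span)
  post_start <- antagonist_onset + settle
  if (post_start >= t_end) stop("post-antagonist window is empty; reduce 'settle'")
  seg_pre <- event_free_segments(trace, events, c(pre_start, antagonist_onset),
                                 required_total)
  seg_post <- event_free_segments(trace, events, c(post_start, t_end),
                                  required_total)
  i_pre <- .mean_over_intervals(trace, seg_pre)
  i_post <- .mean_over_intervals(trace, seg_post)
  structure(list(I_pre = i_pre, I_post = i_post,
                 tonic_amplitude = i_post - i_pre,
                 seconds_used_pre = sum(seg_pre[, 2] - seg_pre[, 1]),
                 seconds_used_post = sum(seg_post[, 2] - seg_post[, 1]),
                 segments_pre = seg_pre, segments_post = seg_post),
            class = "tonic_result")
}

#' @export
print.tonic_result <- function(x, ...) {
  cat(sprintf("tonic amplitude: %.2f pA (I_pre = %.2f, I_post = %.2f pA)\n",
              x$tonic_amplitude, x$I_pre, x$I_post))
  cat(sprintf("  event-free time used: %.2f s pre, %.2f s post\n",
              x$seconds_used_pre, x$seconds_used_post))
  invisible(x)
}
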