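#' Uniformly sampled electrophysiology trace
#'
#' Lightweight container for a uniformly sampled current or voltage time
#' series.  All signal operations in the package (peak measurement, event
#' detection, tonic baseline analysis) consume this class.
#'
#' @param samples Numeric vector of sample values.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param units Character unit label, e.g. `"pA"` or `"uV"`.
#' @param channel Optional channel label.
#' @param t0 Time of the first sample in seconds (default 0).
#'
#' @return An object of class `"ephys_trace"`: a list with elements
#'   `samples`, `sampling_rate`, `units`, `channel`, `t0`.
#' @examples
#' tr <- ephys_trace(rnorm(1000), 1000, "pA")
#' trace_duration(tr)
#' @export
ephys_trace <- function(samples, sampling_rate, units, channel = "ch1", t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("'sampling_rate' must be a single positive number (Hz)")
  }
  if (missing(units) || is.null(units) || !nzchar(units)) {
    stop("trace 'units' are required (e.g. \"pA\", \"uV\"); refusing unit-less data")
  }
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         units = as.character(units),
         channel = as.character(channel),
         t0 = as.numeric(t0)),
    class = "ephys_trace"
  )
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %s [%s], %d samples @ %g Hz (%.3f s)\n",
              x$channel, x$units, length(x$samples), x$sampling_rate,
              trace_duration(x)))
  invisible(x)
}

#' @export
length.ephys_trace <- function(x) length(x$samples)

#' @rdname ephys_trace
#' @param trace An `ephys_trace`.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$sampling_rate

#' @rdname ephys_trace
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$sampling_rate
}

#' @export
plot.ephys_trace <- function(x, ..., xlab = "time (s)",
                             ylab = paste0("signal (", x$units, ")")) {
  graphics::plot(trace_times(x), x$samples, type = "l",
                 xlab = xlab, ylab = ylab, ...)
}

# index of the sample at (or just after) time t, clamped to the trace
.time_to_index <- function(trace, t, clamp = TRUE) {
  i <- round((t - trace$t0) * trace$sampling_rate) + 1L
  if (clamp) i <- pmin(pmax(i, 1L), length(trace$samples))
  as.integer(i)
}

# sample values within [from, to) seconds
.window_samples <- function(trace, from, to) {
  i1 <- .time_to_index(trace, from)
  i2 <- .time_to_index(trace, to)
  if (i2 < i1) stop("empty window [", from, ", ", to, ")")
  trace$samples[i1:i2]
}
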