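# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately written with different algorithms than the
# package code paths they check.

# recall / precision of detected event times against ground truth
match_events <- function(detected, truth, tol = 0.010) {
  if (length(truth) == 0) {
    return(list(recall = NA_real_,
                precision = if (length(detected) == 0) NA_real_ else 0))
  }
  if (length(detected) == 0) return(list(recall = 0, precision = NA_real_))
  recall <- mean(vapply(truth, function(o) any(abs(detected - o) <= tol),
                        logical(1)))
  precision <- mean(vapply(detected, function(o) any(abs(truth - o) <= tol),
                           logical(1)))
  list(recall = recall, precision = precision)
}

# brute-force discharge oracle: for every spike, grow the run forward one
# spike at a time and emit maximal runs; O(n^2), straightforwardly correct
brute_force_discharges <- function(times, max_isi = 0.2, min_n = 3) {
  n <- length(times)
  out <- NULL
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && (times[j + 1] - times[j]) <= max_isi) j <- j + 1
    if (j - i + 1 >= min_n) {
      out <- rbind(out, c(times[i], times[j], j - i + 1))
    }
    i <- j + 1
  }
  if (is.null(out)) {
    data.frame(onset_s = numeric(), offset_s = numeric(), n_spikes = integer())
  } else {
    data.frame(onset_s = out[, 1], offset_s = out[, 2],
               n_spikes = as.integer(out[, 3]))
  }
}

# circuit oracle for the voltage-clamp generator: solve
#   I = g_l (V - E_l) + g (V - E),  V = V_com - I * Rs
# by damped fixed-point iteration rather than the closed form
circuit_peak_oracle <- function(v_com, g_leak, e_leak, g_gaba, e_rev, rs_mohm) {
  rs <- rs_mohm * 1e-3
  solve_i <- function(g) {
    i <- 0
    for (k in 1:200) {
      v <- v_com - i * rs
      i_new <- g_leak * (v - e_leak) + g * (v - e_rev)
      if (abs(i_new - i) < 1e-12) break
      i <- i + 0.5 * (i_new - i)
    }
    i
  }
  i_base <- solve_i(0)
  i_peak <- solve_i(g_gaba)
  list(response = i_peak - i_base, total = i_peak, baseline = i_base)
}

# planted spike schedule for EEG tests: 50 well-separated spikes after the
# baseline stretch
planted_spike_times <- function(seed = 1, n = 50, start = 35, step = 1.6) {
  withr::with_seed(seed, sort(start + (seq_len(n) - 1) * step +
                                stats::runif(n, 0, 0.5)))
}
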