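#' Nernst-equation parameters for chloride
#'
#' Physical constants and conditions for converting between the GABA-A
#' reversal potential and intracellular chloride.  Chloride valence is
#' fixed at -1, so `E_Cl = (RT/F) ln([Cl-]i / [Cl-]o)`.
#'
#' @param Cl_out Extracellular chloride (mM, > 0).
#' @param temperature Bath temperature in kelvin.  Default 303.15 K
#'   (30 degrees C perfusate).
#' @param R Gas constant, J mol^-1 K^-1.
#' @param F Faraday constant, C mol^-1.
#' @return An object of class `"nernst_params"`.
#' @examples
#' p <- nernst_params(Cl_out = 132.5)
#' nernst_potential(10.9, p)
#' @export
nernst_params <- function(Cl_out, temperature = 303.15,
                          R = 8.314, F = 96485) {
  if (Cl_out <= 0) stop("'Cl_out' must be > 0 mM")
  if (temperature <= 0) stop("'temperature' must be > 0 K")
  structure(list(Cl_out = Cl_out, temperature = temperature,
                 R = R, F = F, z = -1L),
            class = "nernst_params")
}

# RT/F in millivolts
.rt_over_f_mV <- function(params) {
  1000 * params$R * params$temperature / params$F
}

#' Chloride concentration from a reversal potential (Nernst equation)
#'
#' `[Cl-]i = [Cl-]o exp(E_GABA F / (R T))` — the z = -1 form of the Nernst
#' equation, with `E_GABA` in mV.  Strictly increasing in `E_GABA`;
#' exact inverse of [nernst_potential()].
#'
#' @param E_GABA Reversal potential in mV.
#' @param params A [nernst_params()].
#' @return Intracellular chloride in mM.
#' @examples
#' chloride_from_nernst(-70.7, nernst_params(132.5))  # ~8.8 mM
#' @export
chloride_from_nernst <- function(E_GABA, params) {
  stopifnot(inherits(params, "nernst_params"))
  params$Cl_out * exp(E_GABA / .rt_over_f_mV(params))
}

#' Reversal potential from a chloride concentration (Nernst equation)
#'
#' `E = (RT/F) ln([Cl-]i / [Cl-]o)` in mV; exact inverse of
#' [chloride_from_nernst()].
#'
#' @param Cl_in Intracellular chloride in mM (> 0).
#' @inheritParams chloride_from_nernst
#' @return Potential in mV.
#' @export
nernst_potential <- function(Cl_in, params) {
  stopifnot(inherits(params, "nernst_params"))
  if (any(Cl_in <= 0)) stop("'Cl_in' must be > 0 mM")
  .rt_over_f_mV(params) * log(Cl_in / params$Cl_out)
}

#' Series-resistance correction of a command potential
#'
#' `V_corr = V_com - I_clamp x R_s`, the correction for the voltage drop
#' across the uncompensated series resistance.  Units are handled exactly:
#' 1 pA x 1 megaohm = 1 microvolt = 1e-3 mV.
#'
#' @param V_com Command potential, mV.
#' @param I_clamp Clamp current at the measurement sample, pA.
#' @param R_s Series resistance, megaohm (>= 0).
#' @return Corrected membrane potential, mV.
#' @examples
#' correct_series_resistance(-60, 100, 10)  # -61 mV
#' @export
correct_series_resistance <- function(V_com, I_clamp, R_s) {
  if (any(R_s < 0)) stop("series resistance must be >= 0")
  V_com - I_clamp * R_s * 1e-3
}

#' Chloride content of a solution recipe
#'
#' Sums `concentration x chloride stoichiometry` over the salts of a
#' recipe.  Common salts carry built-in stoichiometries; any other salt
#' must declare its own or the function refuses (no silent guessing).
#'
#' @param recipe Named numeric vector of salt concentrations in mM,
#'   e.g. `c(NaCl = 126, KCl = 2.5, CaCl2 = 2)`.
#' @param stoichiometry Optional named numeric vector of Cl- ions per
#'   formula unit, overriding or extending the built-in table.
#' @return Total chloride in mM.
#' @examples
#' chloride_from_solution(c(NaCl = 126, KCl = 2.5, NaH2PO4 = 1.25,
#'                          MgSO4 = 2, CaCl2 = 2, NaHCO3 = 26,
#'                          glucose = 20))  # 132.5 mM
#' @export
chloride_from_solution <- function(recipe, stoichiometry = NULL) {
  if (is.null(names(recipe)) || any(!nzchar(names(recipe)))) {
    stop("'recipe' must be a named vector of salt concentrations (mM)")
  }
  if (any(recipe < 0)) stop("concentrations must be >= 0")
  builtin <- c(NaCl = 1, KCl = 1, CsCl = 1, CaCl2 = 2, MgCl2 = 2,
               HCl = 1, choline_chloride = 1, TEA_Cl = 1, QX314_Cl = 1,
               NaH2PO4 = 0, MgSO4 = 0, Mg2SO4 = 0, NaHCO3 = 0, glucose = 0,
               sucrose = 0, HEPES = 0, EGTA = 0, Mg_ATP = 0, Na2_GTP = 0,
               K_CH3SO3 = 0, K_gluconate = 0, CsOH = 0, KOH = 0, NaOH = 0)
  tab <- builtin
  if (!is.null(stoichiometry)) tab[names(stoichiometry)] <- stoichiometry
  unknown <- setdiff(names(recipe), names(tab))
  if (length(unknown) > 0) {
    stop("unknown salt(s) without declared chloride stoichiometry: ",
         paste(unknown, collapse = ", "))
  }
  sum(recipe * tab[names(recipe)])
}

#' Liquid-junction-potential correction
#'
#' Applies the post-hoc liquid junction potential correction
#' `corrected = measured - LJP`.  With the conventional positive LJP for a
#' KCl pipette in ACSF (+10.5 mV), corrected potentials are more negative
#' than measured ones.  The returned value carries an attribute flag so a
#' second application is refused rather than silently compounding.
#'
#' @param V_measured Measured potential(s), mV.
#' @param ljp Liquid junction potential, mV (e.g. `+10.5`).
#' @return Corrected potential(s), mV, with attribute `ljp_corrected = TRUE`.
#' @examples
#' apply_ljp(-51.1, 10.5)  # -61.6 mV
#' @export
apply_ljp <- function(V_measured, ljp) {
  if (isTRUE(attr(V_measured, "ljp_corrected"))) {
    stop("potential is already junction-corrected; refusing to correct twice")
  }
  out <- as.numeric(V_measured) - ljp
  attr(out, "ljp_corrected") <- TRUE
  out
}

#' Peak evoked current in a trace
#'
#' Baseline-subtracted signed extremum within a response window: the sample
#' of largest absolute deviation from the pre-stimulus baseline mean.
#' Inward currents are negative.
#'
#' @param trace An [ephys_trace()] (current, pA).
#' @param stim_time Stimulus time, s.
#' @param baseline_window Length of the pre-stimulus baseline window, s
#'   (ends at `stim_time`).
#' @param response_window Length of the post-stimulus search window, s.
#' @return Scalar peak response (pA, baseline-subtracted, sign preserved),
#'   with attributes `I_total` (absolute clamp current at the peak sample,
#'   pA) and `peak_time` (s).
#' @export
peak_gaba_current <- function(trace, stim_time, baseline_window = 0.1,
                              response_window = 0.3) {
  stopifnot(inherits(trace, "ephys_trace"))
  t_end <- trace$t0 + trace_duration(trace)
  if (stim_time <= trace$t0 || stim_time >= t_end) {
    stop("stimulus time outside the trace")
  }
  if (stim_time + 1 / trace$sampling_rate + response_window > t_end + 1e-9) {
    stop("response window extends beyond the trace")
  }
  base <- .window_samples(trace, max(trace$t0, stim_time - baseline_window),
                          stim_time)
  b <- mean(base)
  i1 <- .time_to_index(trace, stim_time)
  i2 <- .time_to_index(trace, stim_time + response_window)
  if (i2 <= i1) stop("response window is empty")
  resp <- trace$samples[i1:i2] - b
  k <- which.max(abs(resp))
  out <- resp[k]
  attr(out, "I_total") <- trace$samples[i1 + k - 1L]
  attr(out, "peak_time") <- trace$t0 + (i1 + k - 2L) / trace$sampling_rate
  out
}

#' Measure an I-V relation from stepped-potential traces
#'
#' Runs [peak_gaba_current()] on each sweep of a stepped-potential protocol
#' and assembles the I-V table, applying the series-resistance correction
#' per point.  The correction uses the total clamp current at the peak
#' sample (the current actually producing the voltage drop across R_s);
#' the tabulated response `I_peak` is the baseline-subtracted GABA-evoked
#' current.
#'
#' @param traces Named list of [ephys_trace()] sweeps; names are the
#'   command potentials in mV (as produced by [gen_iv_protocol()]).
#' @param stim_time Stimulus time, s.
#' @param R_s Series resistance, megaohm.
#' @param baseline_window,response_window Passed to [peak_gaba_current()].
#' @return A data.frame with columns `V_com`, `I_peak`, `I_total`, `R_s`,
#'   `V_corr` (one row per sweep).
#' @export
measure_iv <- function(traces, stim_time, R_s = 0, baseline_window = 0.1,
                       response_window = 0.3) {
  if (is.null(names(traces))) stop("'traces' must be named by command potential (mV)")
  v_com <- as.numeric(names(traces))
  if (any(is.na(v_com))) stop("trace names must be numeric command potentials (mV)")
  rows <- lapply(seq_along(traces), function(k) {
    pk <- peak_gaba_current(traces[[k]], stim_time, baseline_window,
                            response_window)
    data.frame(V_com = v_com[k], I_peak = as.numeric(pk),
               I_total = attr(pk, "I_total"), R_s = R_s,
               V_corr = correct_series_resistance(v_com[k],
                                                  attr(pk, "I_total"), R_s))
  })
  do.call(rbind, rows)
}
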