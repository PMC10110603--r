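---
title: "Methods: chloride homeostasis and EEG analysis with chloropatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chloride homeostasis and EEG analysis with chloropatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chloropatch)
```

## Scope

chloropatch implements the quantitative layer of a neuronal
chloride-homeostasis study: estimating the GABA~A~ reversal potential
(E~GABA~) and intracellular chloride from gramicidin perforated-patch
current–voltage protocols, quantifying miniature postsynaptic currents and
tonic GABA~A~ currents from whole-cell recordings, detecting epileptiform
spikes and discharges in chronic EEG with a small set of explicit rules,
computing relative band powers over awake epochs, and the behavioral index
and variance-conditional statistics that accompany such studies.  Every
stage is validated end to end against seeded synthetic data with known
ground truth, so the pipeline is testable without any recorded data.

## The clamp model

A voltage-clamped neuron with an uncompensated series resistance R~s~ sees
a membrane potential that differs from the command potential: the clamp
current I drops I·R~s~ across the access pathway.  The package models the
recorded sweep with a leak conductance g~leak~ (reversal E~leak~) and a
transient GABA~A~ conductance g~GABA~(t) (reversal E~rev~), solved
self-consistently per sample:

$$ I = g_{leak}(V - E_{leak}) + g_{GABA}(t)(V - E_{rev}), \qquad
   V = V_{com} - I R_s . $$

This system is linear and solved in closed form by the generator
(`gen_iv_protocol()`).  The analysis side undoes exactly this error with

$$ V_{corr} = V_{com} - I_{clamp} \times R_s $$

(`correct_series_resistance()`), with exact unit bookkeeping
(pA × MΩ = µV).  The correction uses the *total* clamp current at the peak
sample — the current that actually produces the ohmic drop — while the
fitted quantity is the baseline-subtracted GABA-evoked peak.  With that
convention the noiseless corrected I–V is exactly linear and crosses zero
at E~rev~, which the test suite asserts to below a microvolt; correcting
with the baseline-subtracted response instead would leave a leak-dependent
residual bias.

The reversal potential is the zero crossing of a least-squares straight
line through peak current versus corrected potential (`fit_reversal()`).
A GABA~A~ I–V is approximately ohmic near reversal over the usual ±30 mV
span; the fit is deliberately first-order, and residual RMS plus an
extrapolation flag expose situations where that assumption fails.  If the
measured currents never change sign, the fitted reversal may lie at most
10 mV beyond the sampled span; anything further is refused rather than
extrapolated.  Whether practitioners fit a line, a polynomial, or
interpolate between bracketing points varies between laboratories; the
straight line is this package's documented choice, and the diagnostics are
there to justify it per recording.

Chloride follows from the Nernst relation for a pure Cl^−^ conductance
(z = −1):

$$ [\mathrm{Cl}^-]_i = [\mathrm{Cl}^-]_o \exp\!\left(\frac{E_{GABA} F}{RT}\right),
   \qquad
   E_{Cl} = \frac{RT}{F}\ln\frac{[\mathrm{Cl}^-]_i}{[\mathrm{Cl}^-]_o}, $$

with R = 8.314 J mol^−1^ K^−1^, F = 96485 C mol^−1^, and a default bath
temperature of 303.15 K (30 °C perfusate), all overridable through
`nernst_params()`.  HCO~3~^−^ permeability of the GABA~A~ receptor is
deliberately ignored: E~GABA~ is treated as a pure chloride potential,
which is the assumption implicit in any Nernst-based [Cl^−^]~i~ estimate.
The forward and inverse conversions are exact inverses (tested to 10^−9^
relative).  Mean [Cl^−^]~i~ over cells is *not* the Nernst image of the
mean E~GABA~ (the map is convex), so group summaries should be computed
per cell first.

Extracellular chloride is tallied from the solution recipe by
stoichiometry (`chloride_from_solution()`): a standard ACSF with 126 mM
NaCl, 2.5 mM KCl and 2 mM CaCl~2~ carries 132.5 mM Cl^−^.  Unknown salts
are an error, never a silent guess.  Liquid-junction corrections
(`apply_ljp()`) subtract the stated LJP (corrected = measured − LJP, so a
+10.5 mV LJP makes potentials more negative); the returned value carries a
flag so applying the correction twice is refused.

## Synthetic data: what it emulates, and what it does not

All generators derive per-stage sub-streams from one root seed and are
byte-reproducible.  They emulate the features the analysis rules key on:

* `gen_iv_protocol()` — stepped-potential GABA responses with leak,
  series-resistance distortion, and additive white Gaussian noise.
* `gen_mini_trace()` — homogeneous Poisson miniature events, each a
  difference-of-exponentials transient `exp(-t/τ_d) - exp(-t/τ_r)`
  normalized to unit peak on the sampling grid, in white noise.
* `gen_tonic_trace()` — a holding current with superimposed minis that are
  suppressed after antagonist arrival, and a baseline step toward 0 pA.
  The step settles along a raised cosine of finite duration (default 2 s)
  and is *complete* afterwards, so a noiseless recovery is exact to
  machine precision; a first-order exponential never finishes settling and
  would make that exactness test meaningless.
* `gen_eeg()` — background synthesized in the frequency domain with a
  piecewise-flat spectrum over 1–30 Hz matching the requested
  delta/theta/alpha/beta mixture, random phases, fixed per-bin amplitudes
  (so the realized spectral content matches the target exactly at native
  resolution), a low 1/f-style tail outside the analysis range with a
  steep roll-off above 30 Hz, biphasic spike transients (~60 ms, sharp
  negative lobe then a smaller rebound) and flat-topped slow artifacts
  (> 200 ms) at stated times.

Real recordings additionally contain capacitance transients, baseline
drift, non-stationary noise, amplitude-variable minis, movement artifacts
of every shape, and genuinely Gaussian (hence spectrally fluctuating)
backgrounds.  Passing the recovery tests therefore demonstrates that the
*rules are implemented correctly and are recoverable under their stated
assumptions*, not that the defaults are optimal for any particular rig's
data — thresholds and windows are exposed as parameters for that reason.

## Miniature-event analysis

Detection (`detect_minis()`) automates what is often done by eye: the
polarity-aligned, baseline-subtracted signal (running-median baseline,
0.5 s window) must exceed 3.5 robust noise SDs.  The noise SD is a median
absolute deviation, which sparse events do not inflate the way a naive SD
would.  Design points that matter in practice:

* the detection copy of the signal is smoothed with a 0.5 ms moving
  average and a candidate must stay above threshold for ≥ 1 ms — white
  noise essentially never does, a synaptic event always does;
* supra-threshold runs separated by less than the 5 ms refractory are
  fused (a decaying tail hovering at threshold is one event, not five);
* fused runs holding several superimposed events are split at valleys
  between smoothed peaks, but only when both peaks rise a full threshold
  height above the valley — noise bumps riding a tail lack that
  prominence;
* each event's analysis window stops at the next event, so neighbors
  cannot contaminate its peak or decay fit.

Amplitude is measured as the mean of the raw signal over ±0.5 ms around
the smoothed-peak location, relative to a local pre-onset baseline; this
removes the upward selection bias of a raw max-over-window estimate and is
unbiased to within a few percent on synthetic data at SNR 10.  The 10–90%
rise time is interpolated on the rising limb.  The decay is a
monoexponential time constant fitted (Levenberg–Marquardt) on the falling
limb starting where it first drops below 0.8 of the peak, past the
residual curvature of the rising component; on a noiseless τ~r~ = 2 ms /
τ~d~ = 8 ms template the fitted constant is within 5% of τ~d~.  Whether a
"decay time" means a time constant or a time-to-fraction varies between
tools; the time constant is this package's documented definition.  Events
without ≥ 20 ms of clean tail, or with non-convergent fits, are flagged
and excluded from kinetic means but still count toward frequency, which is
reported as events/s or events/min (`summarize_minis()`).

The paired-pulse ratio (`paired_pulse_ratio()`) is peak~2~/peak~1~ with
each peak measured against a baseline taken just before its own stimulus
(2 ms window, kept short so the residual decay of the first response is
subtracted at its current level) and a 1 ms artifact blank.  With 50 ms
intervals and 30 ms decays this residual-subtraction stays within 2% of
the true ratio.

## Tonic current

The tonic GABA~A~ current is the difference between mean baseline currents
during and before antagonist application, computed only over stretches
devoid of synaptic events: around every detected event,
[onset − 5 ms, onset + 50 ms] is excluded, and clean intervals are pooled
greedily from each window's start until 3 s accumulate (pooling, rather
than requiring one contiguous stretch, is the package's reading of a
"total" requirement).  A 10 s wash-in settle after antagonist onset is
excluded by default.  Sign convention: `tonic_amplitude = I_post − I_pre`,
positive when the baseline shifts outward (toward 0 pA from a negative
holding current), i.e. positive values measure the standing inward tonic
current that the antagonist blocked.  The suite demonstrates *why* the
event-free restriction exists: with dense minis, naive whole-window means
are biased by the analytic per-event charge (rate × amplitude × template
integral), while event-free means are not.

## EEG rules

Spike detection applies a fixed rule set (`spike_detection_params()`):

* threshold = 4 × SD of the signal over a user-annotated non-REM baseline
  interval (sleep staging is out of scope; the annotation keeps the rule
  faithful);
* the rectified signal is scanned for contiguous supra-threshold
  excursions in either polarity — polarity is not part of the rule;
* excursions separated by < 25 ms are one waveform (a spike's rebound lobe
  is not a second spike), excursions shorter than 4 ms are discarded as
  noise blips, and waveforms longer than 200 ms are rejected as artifacts;
* the spike time is the rectified extremum; duration is the time between
  threshold crossings.

Discharges are maximal runs of ≥ 3 spikes whose consecutive inter-spike
intervals are all ≤ 200 ms (`group_discharges()`, verified exactly against
a brute-force run enumerator).  The alternative reading — three spikes
inside a single 200 ms window — would be stricter; the inter-spike-interval
reading is the default here.  Discharge burden is reported as a rate per
hour alongside the raw count and analyzed duration
(`discharge_rate()`), so any alternative normalization can be recomputed.

Band powers (`relative_band_powers()`) use a segment-averaged periodogram
(Welch) per epoch: 2 s Hann windows, 50% overlap, mean detrended.
Band power integrates the density over half-open intervals δ [1, 4),
θ [4, 9), α [9, 13), β [13, 30) Hz, and relative power divides by the sum
of the four bands, so the four relative powers sum to 1 by construction
(tested to 10^−12^).  Choices worth knowing:

* the denominator (sum of the four bands) is a package decision that makes
  the normalization testable; a total-power denominator would change
  absolute values but not comparisons between groups;
* a 2 s Hann window has a ±0.5 Hz main lobe, which redistributes a few
  percent of power across sharp band edges.  That is irrelevant for
  smooth spectra but visible against the generator's piecewise-flat
  targets, so the generator-contract validation uses 6 s windows and a
  450 s recording (50 nine-second epochs); the window length is a plain
  argument;
* ten 9 s epochs of white noise pin each band's relative power only to
  about ±0.01–0.02 (the realized spectral content of 90 s of noise
  genuinely fluctuates that much); tolerances in the validation suite are
  set accordingly, not as claims about estimator precision.

## Statistics layer

`discrimination_index()` is (N~N~ − N~F~)/(N~N~ + N~F~) over novel/familiar
exploration counts, exactly antisymmetric under swapping.

`variance_ratio_test()` puts the larger sample variance in the numerator
(F ≥ 1, degrees of freedom matched to the ordering) and doubles the
upper-tail F probability for a two-sided p (capped at 1); a one-sided
option exists.  A summary-statistic mode accepts a precomputed (F, df)
pair so published values can be checked without raw data — e.g.
`variance_ratio_test(f = 3.128, df = c(25, 26))` gives p = 0.005244.  Its
type-I error is calibrated by simulation in the suite (10^4^ null
replicates at n = 27/26, ±0.007 of nominal 0.05).

`welch_conditional_ttest()` encodes a common reporting policy: run the
variance test first, then use Welch's unequal-variance t test when it is
significant (α = 0.05 by default) and the pooled Student t test otherwise.
With equal group sizes the two statistics coincide (only the degrees of
freedom differ), which the suite asserts to 10^−12^.  Repeated-measures
ANOVA families and post-hoc procedures are deliberately out of scope:
pipelines should call the standard implementations directly.

## Numerical and engineering choices

* All signal containers carry explicit units; unit-less files are refused
  at load time rather than guessed.
* Traces travel as two-column delimited text plus a `key: value` sidecar;
  EEG can also travel as standard 16-bit EDF through the built-in
  minimal reader/writer (round-trip tested against the 16-bit
  quantization step; files read back identically in third-party EDF
  tools).
* `run_pipeline()` executes stages from a YAML configuration, echoes every
  tunable plus the seed into the report, and is bit-reproducible under a
  fixed configuration; a failing stage is recorded with its diagnostic
  without voiding the others.
* Problem sizes in the validation suite — 200 replicates per
  reversal-recovery condition, 300 s mini traces, 120 s EEG records,
  10^4^-replicate null calibrations — were chosen to make Monte-Carlo
  margins comfortable while keeping a full run around a minute.

## Known limitations

* The linear I–V model will mis-estimate strongly rectifying responses;
  inspect `residual_rms_pA` and the plot method.
* Detection parameters are tuned for the synthetic SNR regime
  (amplitude ≈ 10 × noise SD); low-SNR recordings need different
  thresholds, and genuinely overlapping events closer than the refractory
  are counted as one.
* The EDF writer covers continuous single-rate recordings only (no EDF+
  annotations, one data record per second).
* The EEG background surrogate is stationary; drifting or state-dependent
  real EEG will make a single non-REM baseline SD less representative
  than it is here.
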