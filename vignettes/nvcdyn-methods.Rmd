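---
title: "Methods: neurovascular coupling dynamics in nvcdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neurovascular coupling dynamics in nvcdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcdyn)
```

# The problem

Sensory stimulation triggers a local rise in neuronal activity that is
followed, within a second or so, by dilation of upstream arterioles and an
increase of red-blood-cell (RBC) velocity in capillaries — functional
hyperemia. `nvcdyn` implements the quantitative chain needed to study the
*dynamics* of this coupling from two-photon line-scan recordings:

1. extract vessel diameter and RBC velocity from line-scan kymographs;
2. normalize per-trial traces (delta-F, percent change, baseline z-score)
   and average them;
3. estimate response onset latencies by four-parameter sigmoid fitting;
4. estimate a gamma-variate transfer function (TF) from neuronal
   calcium to the vascular signal and use it for cross-prediction;
5. quantify spontaneous ~0.1 Hz vasomotion (bandpower, phase at stimulus
   onset).

Every stage is validated by recovery against a synthetic-data generator with
known ground truth, because the in-vivo recordings this kind of analysis
targets are not available in machine-readable form.

# The synthetic-data generator

`ground_truth()` fixes all generative parameters; identical truth (including
the seed) yields bit-identical data.

* **Calcium trace** (`make_calcium_trace()`): zero-mean baseline; after
  stimulus onset (plus a short `ca_onset` latency) the response follows a
  double exponential, `(1 - exp(-u/tau_rise))` rising during the stimulus
  and decaying with `tau_decay` afterwards, normalized so the noiseless peak
  equals `ca_peak_amplitude`. Defaults `tau_rise = 0.2` s, `tau_decay = 1` s
  are GCaMP6s-like; the indicator kinetics are configurable because they are
  not a fitted quantity here.
* **Vascular trace** (`make_vascular_trace()`): the causal convolution of
  the calcium trace with the ground-truth kernel (scaled by the sample
  interval), plus a vasomotion sinusoid `A sin(2 pi f t + phase)` and
  i.i.d. Gaussian noise. Note the *generated* (noisy) calcium trace is
  convolved: spontaneous calcium fluctuations drive the vessel through the
  same kernel as the evoked response, which is both physiologically sensible
  and what makes the kernel identifiable from a single trial (a noiseless
  stimulus-locked input is spectrally poor).
* **Kymographs** (`render_kymograph()`): diameter mode draws a bright
  plateau whose half-maximum edges sit exactly at the true lumen
  boundaries, blurred with a 0.3 um Gaussian; velocity mode draws a bright
  plasma line with moving Gaussian RBC shadows whose displacement per line
  is the instantaneous velocity times the line period.

**Default study conditions.** Vascular traces are expressed in
percent-change-from-baseline units. The default kernel has shape 1.3, rate
0.5 /s, delay 0.27 s — slow, anesthetized-like dynamics (mode at 0.87 s) —
with its gain set to 6 so that a unit-amplitude calcium response evokes a
~5% dilation, matching the few-percent dilations typical of cortical
arterioles. Vasomotion defaults to a single 0.1 Hz sinusoid of 1% amplitude
(an optional roughness of real vasomotion spectra is *not* modeled), and
measurement noise to 0.2%. Trial traces default to 10 Hz sampling;
kymographs to a 1 kHz line rate, which resolves both vasomotion and RBC
streaks. Signal-to-noise in the recovery simulations is defined
generator-level as `ca_peak_amplitude / noise_sd`.

What the generator does **not** emulate: photon-scale imaging noise, motion
artifacts, multi-vessel cross-talk, nonlinear or state-dependent coupling,
1/f vasomotion spectra (a pure sinusoid is used), and adaptation unless
explicitly imposed. Passing recovery tests therefore demonstrates
correctness of the estimators under the stated statistical structure, not
robustness to every pathology of real data.

# Kymograph extraction

**Diameter** (`extract_diameter()`): per scan line, the lumen diameter is
the distance between the two half-maximum crossings of the intensity
profile, with linear interpolation between pixels. The half-maximum level
is midway between a background estimate (mean of the lowest intensity
decile) and the profile maximum, which makes the measurement invariant to
global intensity scaling and offsets. A causal (preceding-time) 200 ms
moving mean is applied to the image first, so the value at time *t* depends
only on lines at times at or before *t*. Lines with no crossing (flat
profile, contrast below 0.05) are returned missing with quality 0.

**Velocity** (`extract_velocity()`): RBC shadows form streaks whose slope
is distance over time. Over sliding windows (default 50 ms, 75% overlap)
the dominant streak slope is found by a Radon-style search: pixel values
are binned on `u = x - s t` for candidate slopes `s` and the slope
maximizing the variance explained by the bin means is selected. The slope
grid is log-spaced in velocity (0.02 px/line up to the slope of the
`v_max` bound) on both signs, because a uniform angle grid cannot resolve
fast streaks — at 20 mm/s with 0.2 um pixels and a 1 kHz line rate the
slope is 100 px/line, an angle within a degree of horizontal. The coarse
maximum is refined on a local 15-point angle grid and by parabolic
interpolation. Velocity is `tan(angle) * dx / dt_line`, signed by flow
direction; quality is the explained-variance fraction, and windows below
0.05 are missing. Round-trip accuracy on rendered kymographs is well below
the 3% (diameter) and 5% (velocity) targets across 2–20 um and
0.2–20 mm/s.

**Activation maps** (`activation_map()`): per pixel, the summed
fluorescence change over the stimulation window relative to the mean
baseline, clipped at zero; the mask keeps pixels at or above
`threshold_frac` (default 0.75) of the maximum score. The threshold is
relative, so the mask is invariant to intensity scaling.

# Trial normalization

All traces are `trial_trace()` tibbles carrying stimulus timing and the
baseline window (half-open, ending at stimulus onset; 9.5 s is the
anesthetized-protocol default in `nvc_config()`, and the full pre-stimulus
period is used when no length is given). `delta_f()` subtracts the baseline
mean; `percent_change()` divides by it (erroring on a zero baseline rather
than emitting NaN); `zscore_trial()` divides the centred trace by the
baseline *sample* SD (n-1 denominator). Missing samples (quality-0
kymograph lines) are excluded from baseline statistics and linearly
interpolated for whole-trace operations.

Z-scoring is the heart of the onset analysis: trials with large spontaneous
vasomotion have large baseline SDs, so their evoked responses are
down-weighted when z-scored trials are averaged (`average_trials()`, which
also reports the pointwise SEM). The response amplitude of a trial is the
maximum inside the response window (stimulus onset to offset + 2 s; a peak
rather than a window mean, which is the less ambiguous reading of
"response amplitude" for monotone rises). `intertrial_variability()` is the
sample SD of these amplitudes; `adaptation_check()` returns the first three
amplitudes in presentation order.

# Sigmoid onset estimation

Averaged z-score traces are fit (`fit_sigmoid()`) with

$$s(x) = A + \frac{B}{1 + e^{-(-x - C)\,D}}$$

by least squares, using a deterministic multi-start grid (three midpoint
starts across the window; `|D|` in {0.5, 1, 2, 5} /s; both signs) refined
by Levenberg-Marquardt, keeping the minimum-RSS fit. As printed, this
parameterization is degenerate under `(A, B, C, D) -> (A + B, -B, C, -D)`;
fits are canonicalized to `B > 0`, under which a *rising* response has
`D < 0`. The reported rising slope is the signed `D`; comparisons use
`|D|`.

Onsets (`onset_times()`) come from the closed-form sigmoid inverse: the
peak is the upper asymptote minus the baseline level (the fitted lower
asymptote by default; the empirical baseline mean is available as an
option), and `tXX` is the earliest time the fit reaches XX% of that peak,
reported relative to stimulus onset. Degenerate cases are flagged rather
than guessed: flat traces return an unidentifiable slope, non-rising fits
return `ok = FALSE`.

The default fit window runs from the baseline start to stimulus offset
plus 5 s. For slowly decaying responses the sigmoid cannot represent the
post-peak decay, which biases `t25` late by up to about one sample; when
that matters, pass a rising-phase window ending at the response peak
(`fit_window = c(start, t_peak)`), as the recovery tests do. With that
window, noiseless `t25` recovery is within one 10 Hz sample of the
model-free 25%-crossing, and across 100 noisy averaged trial sets the
median `t25` error is ~0.15 s.

# The transfer function

The coupling kernel is a delayed gamma-variate

$$\mathrm{TF}(t) = H(t - p_3)\, p_4\,
  \frac{(t - p_3)^{p_1 - 1} p_2^{p_1} e^{-p_2 (t - p_3)}}{\Gamma(p_1)},$$

i.e. gain `p4` times a unit-mass gamma density (shape `p1`, rate `p2`)
delayed by `p3`. Its integral is `p4` and, for `p1 > 1`, it is zero at
onset with a unique mode at `p3 + (p1 - 1)/p2`. Evaluation uses the exact
density (`dgamma`); predictions are causal discrete convolutions scaled by
the sample interval, computed by FFT with the kernel truncated at 60 s or
where the tail falls below 1e-8 of its peak (quadrature-verified against a
20x-refined oracle to within 1%).

`fit_tf()` minimizes the residual sum of squares between the vascular trace
and the convolution prediction (equivalently maximizes R^2 — the published
protocol's "smallest coefficient of determination" is read as the best
residual, since the smallest R^2 would be the worst kernel). Optimization
follows the published protocol: bounded simulated annealing initialized at
(1.3, 0.5, 0.27, 0.19), two rounds of 200 runs, the second round seeded at
the best of the first. Plausibility is enforced as box bounds — `p1` in
(1, 10], `p2` in (0, 20] /s, `p3` in [0, 5] s, `p4` in (0, 100] — chosen to
enclose the initial values with wide margins; `p1 > 1` realizes the
requirements that the kernel be zero at time zero and have no
non-differentiable point after onset. Each annealing run uses Gaussian
proposals with a temperature-scaled step (15% of the box span, cooled
geometrically by 0.95 per iteration, 500 iterations), reflection at the
bounds, and Metropolis acceptance; runs differ only by their RNG stream,
derived deterministically from the fit seed, so a fixed seed gives
bit-identical fits. A Nelder-Mead polish of the annealing optimum is on by
default. The recovery simulations and the pipeline default use a reduced
schedule (2 rounds of 8–20 runs, 150–200 iterations) — at these problem
sizes (30 s traces at 10 Hz) it reaches the same optimum as the full
protocol in a fraction of the time, as the noiseless round-trip test
verifies to within 2% of the kernel peak.

Cross-prediction (`cross_predict()`) applies a kernel to a different
dataset: the predicted amplitude is rescaled by the closed-form
least-squares factor `a = <obs, pred> / <pred, pred>`, and quality is
reported as the Pearson correlation (invariant to the rescaling) plus R^2.
`compare_states()` runs paired cross-predictions with two kernels over a
set of networks and extracts each prediction's rising slope via the sigmoid
fit — the comparison used to contrast brain states.

`reproduce_state_contrast()` is the synthetic twin of that contrast: an
anesthetized-like ensemble (slow kernel, mode 0.87 s, 5 s stimulus) and an
awake-like ensemble (fast kernel, rate 2 /s and delay 0.1 s, mode 0.25 s,
3 s stimulus) are simulated under the default study conditions; a TF is fit
to each ensemble mean and both are cross-applied to every awake-like
network. The matched fast kernel achieves strictly higher Pearson r and
larger `|D|` on every network (20 by default).

# Vasomotion

`bandpower()` computes the average power of the mean-removed baseline in
0.02–1 Hz from a rectangular-window periodogram, summing the one-sided
per-ordinate powers `2 |X_k|^2 / N^2` in the band; for an in-band sinusoid
of amplitude A this converges to A^2/2, the analytic mean-square, which is
how the convention is tested. `lowpass()` is a zero-phase (forward-
backward) 4th-order Butterworth with unit DC gain; mean removal and
odd-reflection padding suppress edge transients so a constant trace passes
through exactly. The realization is deliberately pinned by its contract —
passband preservation within 5% and stopband attenuation of at least 90% at
five times the cutoff — rather than by the filter family.

`classify_phase()` inspects the lowpassed (0.2 Hz) percent-change trace in
a 2.5 s window ending at stimulus onset (a quarter cycle at 0.1 Hz):
above/below is the filtered window mean against the mean of the filtered
baseline (the filtered mean is the default reference; the raw mean is an
option), ascending/descending is the endpoint difference across the window
(an endpoint difference, not a regression slope, as the plainest reading of
"ascending"). Phases: 1 above/ascending, 2 above/descending, 3
below/descending, 4 below/ascending. Exact ties resolve to the lower phase
number and are flagged, preserving auditability. Over a uniform grid of
sinusoid phase offsets the four classes partition the circle into quarters.

`power_response_correlation()` is the Pearson correlation between per-trial
baseline bandpower and a response metric. In a simulation where the
absolute evoked response is independent of the vasomotion amplitude,
percent-change amplitudes correlate positively with bandpower while z-score
amplitudes do not (the baseline SD in the denominator grows with
vasomotion) — the sign contrast the normalization is designed to produce.

# The pipeline

`nvc_run()` executes simulate-or-load, normalization, onset, TF and
vasomotion stages in order, materializes every intermediate artifact as
CSV/JSON under the output directory (runs are never in-memory-only, for
auditability), emits one structured log line per stage, and returns a
report whose JSON payload is byte-identical across runs with the same
config and seed. `nvc_config()` carries the two stimulus protocols
(5 Hz/5 s anesthetized-like, 90 Hz/3 s awake-like; the deflection rate is
metadata — it does not enter the trace model), the 9.5 s anesthetized
baseline default, onset levels, TF bounds/seeds and vasomotion settings.
The awake baseline length is deliberately a free parameter (the full
pre-stimulus period by default) rather than a fixed constant.

# Numerical choices and limitations

* Sample SD (n-1) throughout; windows half-open `[start, end)`; time in
  seconds from trial start; 0-based pixel indexing in physical units
  (pixel centres at `(i - 0.5) dx`).
* The FFT convolution and the 1e-8-of-peak kernel truncation introduce
  absolute errors below 1e-7 of typical trace values.
* Degenerate inputs error loudly (zero baseline mean for percent change,
  zero baseline SD for z-scores, unresolvable bands, incomplete phase
  windows) or are flagged (flat sigmoid fits, tied phases, quality-0
  lines) — never silently imputed.
* The TF model is linear and stationary by construction; it cannot
  represent state-dependent or nonlinear coupling, and the fitted gain
  absorbs any amplitude mismatch, which is why prediction quality is
  assessed with the amplitude-invariant Pearson r.
* Velocity extraction assumes a single dominant flow direction per window;
  stalled cells yield zero velocity, but bidirectional flow within one
  window is unmodeled.
* Runtime-motivated problem sizes: recovery suites use 30 s traces at
  10 Hz, 50-replicate noise studies, and the reduced annealing schedule;
  kymograph round-trips use 0.25–0.4 s records at 1 kHz. These sizes are
  stated here so they can be scaled up when more compute is available.
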