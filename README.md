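# nvcdyn

Analysis of **neurovascular coupling (NVC) dynamics** from two-photon
line-scan imaging: how fast, and through what linear kernel, does a rise in
neuronal Ca²⁺ translate into arteriole dilation and capillary red-blood-cell
(RBC) velocity increases?

The package is aimed at labs doing in vivo two-photon imaging of the
cortical microvasculature (line-scan kymographs of vessels, GCaMP calcium
reporters, sensory stimulation protocols) who want a tested, reproducible
implementation of the full analysis chain:

* **Kymograph extraction** — vessel lumen diameter from sub-pixel
  half-maximum boundaries of the labeled-plasma profile (with a causal
  200 ms mean filter), and RBC velocity from the slope of RBC shadow
  streaks via a Radon-style projection-variance search; thresholded
  widefield activation maps.
* **Trial normalization** — ΔF, percent change from baseline, and per-trial
  baseline z-scores (sample SD), with trial averaging, inter-trial
  variability (SD of response amplitudes) and adaptation checks.
* **Onset latency** — least-squares fit of the four-parameter sigmoid
  *s(x) = A + B / (1 + exp(−(−x − C)·D))* to averaged z-score traces;
  onset times t10/t25/t50 at 10/25/50% of the fit peak from the closed-form
  sigmoid inverse; rising slope defined as the D parameter.
* **Transfer function** — the delayed gamma-variate kernel
  *TF(t) = H(t−p₃)·p₄·((t−p₃)^(p₁−1) p₂^(p₁) e^(−p₂(t−p₃)) / Γ(p₁))*
  fit by bounded simulated annealing (two rounds of restarts, plausibility
  bounds with p₁ > 1), convolution-based prediction with closed-form
  amplitude rescaling, Pearson-r prediction quality, and paired
  brain-state comparisons (fast awake-like vs slow anesthetized-like
  kernels).
* **Vasomotion** — 0.02–1 Hz baseline bandpower from a periodogram,
  zero-phase 0.2 Hz lowpass, and four-class vasomotion phase at stimulus
  onset (above/below baseline × ascending/descending in a 2.5 s
  pre-stimulus window).
* **Synthetic data** — a ground-truth generator (stimulus-locked GCaMP-like
  responses, kernel-convolved vascular traces, sinusoidal vasomotion,
  rendered kymographs with moving RBC shadows) so that every stage is
  validated by recovery against known truth.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

Simulate an anesthetized-like experiment (12 trials, 5 s whisker
stimulation, slow coupling kernel, 1% vasomotion, 0.2% noise), then run the
onset and transfer-function analyses:

```r
library(nvcdyn)

gt  <- ground_truth(seed = 42)          # slow kernel, mode at 0.87 s
set <- simulate_trial_set(12, gt)       # paired calcium / diameter trials

mean_z  <- average_trials(lapply(set$vascular, zscore_trial))
fit     <- fit_sigmoid(mean_z)
onset_times(fit, stim_onset = 10)
#> # A tibble: 1 × 6
#>     t10   t25   t50  peak slope ok
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1 0.968  1.40  1.84  5.72 -2.53 TRUE
```

The dilation reaches 25% of its fitted peak 1.40 s after stimulus onset
(the onset statistic used throughout), with a peak of 5.7 z-units and a
rising slope (D parameter) of −2.5 /s.

```r
mean_ca <- average_trials(lapply(set$calcium, delta_f))
tf <- fit_tf(mean_ca, mean_z,
             control = tf_control(rounds = 2, runs = 20, iters = 200),
             seed = 1)
tf
#> <gamma-variate transfer function>
#>   shape p1 = 1.075, rate p2 = 0.5267 /s, delay p3 = 0.6991 s, gain p4 = 8.701
#>   mode at 0.8412 s, grid_dt = 0.1 s
cross_predict(tf, mean_ca, mean_z)[, c("scale", "pearson_r", "r2")]
#> # A tibble: 1 × 3
#>   scale pearson_r    r2
#>   <dbl>     <dbl> <dbl>
#> 1 1.000     0.990  0.979
```

The fitted kernel peaks 0.84 s after the calcium rise (true generative mode:
0.87 s — individual parameters trade off, the kernel shape is what is
identified), and convolving it with the calcium trace predicts the vascular
trace with Pearson r = 0.99.

The brain-state contrast on synthetic ensembles (fast awake-like vs slow
anesthetized-like kernels, cross-applied to awake-like networks):

```r
res <- reproduce_state_contrast(seed = 1)
plot_state_contrast(res$table)   # matched fast kernel wins on every network
```

See the methods vignette (`vignettes/nvcdyn-methods.Rmd`) for the models,
parameter conventions, and the design decisions behind each stage.

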