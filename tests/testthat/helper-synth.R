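# shared fixture builders; everything is generated in code at test time

quiet_truth <- function(...) {
  # noise- and vasomotion-free truth for exact checks
  ground_truth(vasomotion_amplitude = 0, noise_sd = 0, ...)
}

# an SNR-10 replicate truth: noise at a tenth of the calcium amplitude
snr10_truth <- function(i) {
  ground_truth(vasomotion_amplitude = 0, noise_sd = 0.1, seed = 9000 + i)
}

# independent quadrature oracle for the continuous convolution
# ca(t) (piecewise linear) * kernel: evaluated on a `refine`-times finer grid
# and subsampled back; independent of tf_convolve's FFT path
conv_quadrature_oracle <- function(ca_t, ca_v, tf, refine = 20) {
  dt <- mean(diff(ca_t))
  dtf <- dt / refine
  tf_fine <- seq(ca_t[1], ca_t[length(ca_t)], by = dtf)
  caf <- stats::approx(ca_t, ca_v, xout = tf_fine)$y
  kf <- tf_eval(tf, seq(0, 60, by = dtf))
  n <- length(caf)
  out <- numeric(n)
  # direct (non-FFT) causal sum at fine resolution
  for (i in seq_len(n)) {
    m <- min(i, length(kf))
    out[i] <- sum(caf[i - seq_len(m) + 1] * kf[seq_len(m)]) * dtf
  }
  out[seq(1, n, by = refine)]
}

# first crossing of `frac` of peak above baseline, by linear interpolation --
# the model-free onset oracle
crossing_time <- function(time_s, value, baseline, frac) {
  peak <- max(value) - baseline
  lvl <- baseline + frac * peak
  above <- which(value >= lvl)
  i <- above[1]
  if (i == 1) return(time_s[1])
  time_s[i - 1] + (lvl - value[i - 1]) / (value[i] - value[i - 1]) *
    (time_s[i] - time_s[i - 1])
}

make_flat_trace <- function(v = 2, n = 201) {
  trial_trace(seq(0, by = 0.1, length.out = n), rep(v, n),
              stim_onset = 10, stim_duration = 5, modality = "diameter")
}
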