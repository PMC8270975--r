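mk_trace <- function(value, t = seq(0, 20, by = 0.1), stim = 10, dur = 5) {
  trial_trace(t, value, stim_onset = stim, stim_duration = dur,
              modality = "diameter")
}

test_that("delta_f centres on the baseline mean and is idempotent", {
  tr <- mk_trace(rep(3, 201))
  expect_true(all(delta_f(tr)$value == 0))

  t <- seq(0, 4, by = 1)
  tr2 <- trial_trace(t, c(1, 1, 1, 2, 2), stim_onset = 3, stim_duration = 1)
  expect_equal(delta_f(tr2)$value, c(0, 0, 0, 1, 1))

  tr3 <- mk_trace(rnorm(201))
  expect_equal(delta_f(delta_f(tr3))$value, delta_f(tr3)$value)
})

test_that("percent change is the baseline-relative ratio and scale-invariant", {
  t <- seq(0, 4, by = 1)
  tr <- trial_trace(t, c(4, 4, 4, 4.4, 4), stim_onset = 3, stim_duration = 1)
  expect_equal(percent_change(tr)$value[4], 10)
  expect_true(all(percent_change(mk_trace(rep(7, 201)))$value == 0))

  tr2 <- mk_trace(5 + runif(201))
  tr2b <- trace_update(tr2, 3.7 * tr2$value)
  expect_equal(percent_change(tr2b)$value, percent_change(tr2)$value,
               tolerance = 1e-12)

  expect_error(percent_change(mk_trace(c(rep(0, 150), rep(1, 51)))), "zero")
})

test_that("z-scoring normalizes by the sample SD of the baseline", {
  t <- seq(0, 3, by = 1)
  tr <- trial_trace(t, c(0, 2, 1 + 2 * sqrt(2), 1), stim_onset = 2,
                    stim_duration = 1)
  z <- zscore_trial(tr)
  expect_equal(z$value[3], 2)
  expect_equal(attr(z, "baseline_mean"), 1)
  expect_equal(attr(z, "baseline_sd"), sqrt(2))

  tr2 <- mk_trace(rnorm(201, 5, 2))
  z2 <- zscore_trial(tr2)
  b <- z2$value[z2$time_s < 10]
  expect_lt(abs(mean(b)), 1e-9)
  expect_equal(stats::sd(b), 1)

  expect_error(zscore_trial(mk_trace(rep(1, 201))), "flat")
})

test_that("larger vasomotion shrinks the evoked z for the same response", {
  mk <- function(amp) {
    gt <- ground_truth(vasomotion_amplitude = amp, noise_sd = 0, seed = 6)
    ca <- make_calcium_trace(10, 5, 10, gt)
    zscore_trial(make_vascular_trace(ca, gt))
  }
  z1 <- mk(1); z3 <- mk(3)
  a1 <- max(z1$value[z1$time_s >= 10]); a3 <- max(z3$value[z3$time_s >= 10])
  expect_gt(a1, a3)
  # baseline SD scales with the vasomotion amplitude, so z shrinks ~3x
  # (up to the vasomotion contribution riding on the response peak)
  expect_lt(a3 / a1, 0.5)
  expect_gt(a3 / a1, 0.2)
})

test_that("percent change and z-score agree in shape (both affine)", {
  tr <- mk_trace(5 + cumsum(rnorm(201, 0, 0.1)))
  expect_equal(stats::cor(percent_change(tr)$value, zscore_trial(tr)$value), 1)
})

test_that("trial averaging returns pointwise mean and SEM", {
  tr <- mk_trace(rnorm(201))
  avg <- average_trials(list(tr, tr, tr))
  expect_equal(avg$value, tr$value)
  expect_true(all(avg$sem == 0))

  neg <- trace_update(tr, -tr$value)
  avg2 <- average_trials(list(tr, neg))
  expect_true(all(abs(avg2$value) < 1e-12))
  expect_equal(avg2$sem, abs(tr$value) * sqrt(2) / sqrt(2),
               tolerance = 1e-9)

  shifted <- trial_trace(tr$time_s + 1, tr$value, stim_onset = 11,
                         stim_duration = 5)
  expect_error(average_trials(list(tr, shifted)), "time base")
})

test_that("trial averages converge to the noiseless template as 1/sqrt(n)", {
  template <- local({
    gt <- quiet_truth()
    ca <- make_calcium_trace(10, 5, 10, gt)
    make_vascular_trace(ca, gt)$value
  })
  rmse <- vapply(c(4, 64), function(n) {
    gt <- ground_truth(vasomotion_amplitude = 1e-12, noise_sd = 0.5, seed = 13)
    s <- simulate_trial_set(n, gt)
    sqrt(mean((average_trials(s$vascular)$value - template)^2))
  }, numeric(1))
  # 16x more trials: error should drop by ~4 (allow wide stochastic slack)
  expect_lt(rmse[2], rmse[1] / 2)
})

test_that("inter-trial variability is the SD of window maxima", {
  t <- seq(0, 4, by = 1)
  mk2 <- function(a) trial_trace(t, c(0, 0, a, 0, 0), stim_onset = 1,
                                 stim_duration = 1)
  out <- intertrial_variability(list(mk2(1), mk2(3)))
  expect_equal(out$sd_amplitude, sqrt(2))
  expect_equal(intertrial_variability(list(mk2(2), mk2(2)))$sd_amplitude, 0)
  expect_error(intertrial_variability(list(mk2(1))), "2 trials")
})

test_that("amplitude SD estimates the imposed jitter on synthetic sets", {
  gt <- ground_truth(vasomotion_amplitude = 1e-12, noise_sd = 0.01, seed = 21)
  s <- simulate_trial_set(100, gt, amplitude_jitter_sd = 0.2)
  out <- intertrial_variability(s$vascular)
  # evoked peak ~5 units, jitter sd 0.2 -> amplitude sd ~1
  expect_equal(out$sd_amplitude / out$mean_amplitude, 0.2, tolerance = 0.35)
})

test_that("adaptation check returns leading amplitudes in order", {
  t <- seq(0, 4, by = 1)
  trs <- lapply(c(3, 2, 1, 5), function(a)
    trial_trace(t, c(0, 0, a, 0, 0), stim_onset = 1, stim_duration = 1))
  out <- adaptation_check(trs, k = 3)
  expect_equal(out$amplitude, c(3, 2, 1))
  out_perm <- adaptation_check(trs[c(2, 1, 3, 4)], k = 3)
  expect_equal(out_perm$amplitude, c(2, 3, 1))
  expect_error(adaptation_check(trs[1:2], k = 3), "at least 3")
})
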