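test_that("kernel is zero up to the delay and peaks at the analytic mode", {
  tf <- transfer_function(1.3, 0.5, 0.27, 0.19)
  t_pre <- c(0, 0.1, 0.26, 0.27)
  expect_true(all(tf_eval(tf, t_pre) == 0))
  grid <- seq(0, 30, by = 1e-3)
  expect_lt(abs(grid[which.max(tf_eval(tf, grid))] -
                  (0.27 + (1.3 - 1) / 0.5)), 1e-3 + 1e-9)
  expect_error(transfer_function(-1, 0.5, 0, 1), "p1")
  expect_error(transfer_function(1.3, 0, 0, 1), "p2")
})

test_that("kernel mass equals the gain for any accepted parameter set", {
  t <- seq(0, 120, by = 1e-3)
  for (p in list(c(1.3, 0.5, 0.27, 0.19), c(2.5, 1.5, 0.1, 3),
                 c(1.1, 0.2, 1, 0.7))) {
    tf <- transfer_function(p[1], p[2], p[3], p[4])
    expect_equal(pracma::trapz(t, tf_eval(tf, t)), p[4], tolerance = 1e-3)
  }
})

test_that("discrete prediction matches impulse response and is linear", {
  tf <- transfer_function(1.8, 1, 0.3, 0.5)
  dt <- 0.05
  t <- seq(0, 30, by = dt)
  imp <- tibble::tibble(time_s = t,
                        value = c(1, rep(0, length(t) - 1)))
  pred <- predict(tf, imp)
  # agreement up to FFT roundoff and the 1e-8-of-peak tail truncation
  expect_lt(max(abs(pred$value - tf_eval(tf, t) * dt)), 1e-9)

  a <- tibble::tibble(time_s = t, value = sin(t) + 1)
  b <- tibble::tibble(time_s = t, value = exp(-t / 5))
  ab <- tibble::tibble(time_s = t, value = a$value + b$value)
  expect_equal(predict(tf, ab)$value,
               predict(tf, a)$value + predict(tf, b)$value,
               tolerance = 1e-9)
})

test_that("discrete convolution agrees with a dense quadrature oracle", {
  tf <- transfer_function(1.5, 0.8, 0.3, 1.2)
  dt <- 0.01  # 100 Hz
  t <- seq(0, 30, by = dt)
  gt <- quiet_truth()
  ca_v <- make_calcium_trace(10, 5, 100, gt, duration = 30)$value
  disc <- predict(tf, tibble::tibble(time_s = t, value = ca_v))$value
  oracle <- conv_quadrature_oracle(t, ca_v, tf, refine = 20)
  expect_lt(max(abs(disc - oracle)) / max(abs(oracle)), 0.01)
})

test_that("noiseless recovery: fitted kernel matches truth within 2% of peak", {
  gt <- quiet_truth(tf_params = c(2, 1.2, 0.3, 4))
  ca <- make_calcium_trace(10, 5, 10, gt)
  va <- make_vascular_trace(ca, gt)
  tf <- fit_tf(ca, va, control = tf_control(rounds = 2, runs = 20,
                                            iters = 200), seed = 1)
  grid <- seq(0, 30, by = 0.01)
  ktrue <- tf_eval(truth_tf(gt), grid)
  expect_lt(max(abs(tf_eval(tf, grid) - ktrue)) / max(ktrue), 0.02)
})

test_that("fits are bit-identical under a fixed seed", {
  gt <- ground_truth(seed = 3, noise_sd = 0.3)
  ca <- make_calcium_trace(10, 5, 10, gt)
  va <- make_vascular_trace(ca, gt)
  ctrl <- tf_control(rounds = 1, runs = 5, iters = 100)
  f1 <- fit_tf(ca, va, control = ctrl, seed = 7)
  f2 <- fit_tf(ca, va, control = ctrl, seed = 7)
  expect_identical(c(f1$p1, f1$p2, f1$p3, f1$p4),
                   c(f2$p1, f2$p2, f2$p3, f2$p4))
})

test_that("doubling the vascular data doubles the gain only", {
  gt <- quiet_truth(tf_params = c(1.6, 0.9, 0.2, 2))
  ca <- make_calcium_trace(10, 5, 10, gt)
  va <- make_vascular_trace(ca, gt)
  ctrl <- tf_control(rounds = 2, runs = 15, iters = 150)
  f1 <- fit_tf(ca, va, control = ctrl, seed = 2)
  f2 <- fit_tf(ca, trace_update(va, 2 * va$value), control = ctrl, seed = 2)
  expect_equal(f2$p4, 2 * f1$p4, tolerance = 0.02)
  expect_equal(c(f2$p1, f2$p2, f2$p3), c(f1$p1, f1$p2, f1$p3),
               tolerance = 0.05)
})

test_that("cross-prediction scale has the stated closed form", {
  tf <- transfer_function(1.5, 1, 0.2, 1)
  gt <- quiet_truth()
  ca <- make_calcium_trace(10, 5, 10, gt)
  pred <- predict(tf, ca)

  self <- cross_predict(tf, ca, pred)
  expect_equal(self$scale, 1, tolerance = 1e-12)
  expect_equal(self$pearson_r, 1, tolerance = 1e-12)
  expect_equal(self$r2, 1, tolerance = 1e-12)

  tripled <- cross_predict(tf, ca, trace_update(pred, 3 * pred$value))
  expect_equal(tripled$scale, 3, tolerance = 1e-12)
  expect_equal(tripled$pearson_r, 1, tolerance = 1e-12)

  # brute-force 1-D grid oracle for the scale
  obs <- trace_update(pred, 2.4 * pred$value + rnorm(nrow(pred), 0, 0.1))
  cp <- cross_predict(tf, ca, obs)
  grid <- seq(cp$scale - 0.5, cp$scale + 0.5, length.out = 20001)
  sse <- vapply(grid, function(a) sum((obs$value - a * pred$value)^2),
                numeric(1))
  expect_lt(abs(grid[which.min(sse)] - cp$scale), 1e-4)
})

test_that("pearson r is invariant to scaling and offsets of the observation", {
  tf <- transfer_function(1.4, 0.8, 0.2, 1)
  gt <- ground_truth(seed = 5, noise_sd = 0.3)
  ca <- make_calcium_trace(10, 5, 10, gt)
  va <- make_vascular_trace(ca, gt)
  r0 <- cross_predict(tf, ca, va)$pearson_r
  expect_equal(cross_predict(tf, ca, trace_update(va, 5 * va$value))$pearson_r,
               r0, tolerance = 1e-12)
  expect_equal(cross_predict(tf, ca, trace_update(va, va$value + 2))$pearson_r,
               r0, tolerance = 1e-12)
})

test_that("mode time recovery under noise stays within 10% (seeded replicates)", {
  errs <- vapply(seq(1, 30, by = 2), function(i) {
    gt <- snr10_truth(i)
    ca <- make_calcium_trace(10, 5, 10, gt)
    va <- make_vascular_trace(ca, gt)
    tf <- fit_tf(ca, va, control = tf_control(rounds = 2, runs = 8,
                                              iters = 150), seed = i)
    abs(tf_mode(tf) - tf_mode(truth_tf(gt))) / tf_mode(truth_tf(gt))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("self-prediction is at least as good as a cross-applied kernel", {
  gt <- ground_truth(seed = 11, noise_sd = 0.2, vasomotion_amplitude = 0.5)
  ca <- make_calcium_trace(10, 5, 10, gt)
  va <- make_vascular_trace(ca, gt)
  ctrl <- tf_control(rounds = 2, runs = 15, iters = 150)
  tf_own <- fit_tf(ca, va, control = ctrl, seed = 1)
  tf_other <- transfer_function(1.3, 2.5, 0.05, 6)  # mismatched dynamics
  expect_gte(cross_predict(tf_own, ca, va)$pearson_r,
             cross_predict(tf_other, ca, va)$pearson_r)
})

test_that("compare_states returns identical pairs for identical kernels", {
  gt <- ground_truth(seed = 2, noise_sd = 0.2)
  ca <- make_calcium_trace(10, 3, 10, gt)
  va <- make_vascular_trace(ca, gt)
  tf <- transfer_function(1.3, 2, 0.1, 6)
  out <- compare_states(tf, tf, list(ca), list(va))
  expect_equal(out$r_a, out$r_b)
  expect_equal(out$abs_slope_a, out$abs_slope_b)
})
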