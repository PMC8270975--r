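test_that("diameter extraction finds half-maximum boundaries to sub-pixel accuracy", {
  gt <- quiet_truth()
  dtr <- tibble::tibble(time_s = seq(0, 0.3, by = 0.01), value = rep(4, 31))
  k <- render_kymograph(diameter_t = dtr, dx = 0.2, dt_line = 0.001,
                        truth = gt, mode = "diameter")
  m <- extract_diameter(k)
  expect_true(all(abs(m$value - 4) <= 0.5 * 0.2))
  expect_true(all(m$quality > 0))
})

test_that("diameter extraction is invariant to intensity scale and offset", {
  gt <- ground_truth(noise_sd = 0.02, seed = 8)
  dtr <- tibble::tibble(time_s = seq(0, 0.3, by = 0.01),
                        value = 6 + 0.5 * sin(2 * pi * 3 * seq(0, 0.3, 0.01)))
  k <- render_kymograph(diameter_t = dtr, dx = 0.2, dt_line = 0.001,
                        truth = gt, mode = "diameter")
  m0 <- extract_diameter(k)
  k2 <- k
  k2$image <- 5 * k$image + 2
  m2 <- extract_diameter(k2)
  expect_equal(m2$value, m0$value, tolerance = 1e-12)
})

test_that("all-dark kymograph yields missing lines with zero quality", {
  k <- kymograph(matrix(0, 100, 50), dt_line = 0.001, dx = 0.2,
                 mode = "diameter")
  m <- extract_diameter(k)
  expect_true(all(is.na(m$value)))
  expect_true(all(m$quality == 0))
})

test_that("diameter round-trip error is below 3% across 2-20 um", {
  gt <- ground_truth(noise_sd = 0.02, seed = 5)
  errs <- vapply(c(2, 4, 8, 14, 20), function(d) {
    dtr <- tibble::tibble(time_s = seq(0, 0.25, by = 0.01), value = rep(d, 26))
    k <- render_kymograph(diameter_t = dtr, dx = 0.2, dt_line = 0.001,
                          truth = gt, mode = "diameter")
    m <- extract_diameter(k)
    stats::median(abs(m$value - d) / d, na.rm = TRUE)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.03)
  expect_true(all(errs < 0.03))
})

test_that("mean filter before boundary detection is causal", {
  # a step change in diameter must not influence lines before it occurs
  gt <- quiet_truth()
  tt <- seq(0, 0.4, by = 0.001)
  dtr <- tibble::tibble(time_s = tt, value = ifelse(tt < 0.2, 4, 8))
  k <- render_kymograph(diameter_t = dtr, dx = 0.2, dt_line = 0.001,
                        truth = gt, mode = "diameter")
  m <- extract_diameter(k, filter_ms = 100)
  pre <- m$value[m$time_s < 0.198]
  expect_true(all(abs(pre - 4) < 0.15))
})

test_that("velocity extraction recovers rendered streak slopes within 5%", {
  gt <- ground_truth(noise_sd = 0.02, seed = 5)
  errs <- vapply(c(0.2, 1, 5, 20), function(v) {
    vtr <- tibble::tibble(time_s = seq(0, 0.4, by = 0.01), value = rep(v, 41))
    k <- render_kymograph(velocity_t = vtr, dx = 0.2, dt_line = 0.001,
                          truth = gt, mode = "velocity")
    m <- extract_velocity(k)
    stats::median(abs(m$value - v) / v, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(errs < 0.05))
})

test_that("velocity sign tracks flow direction and stalled cells give zero", {
  gt <- ground_truth(noise_sd = 0.01, seed = 2)
  vtr <- tibble::tibble(time_s = seq(0, 0.3, by = 0.01), value = rep(-2, 31))
  k <- render_kymograph(velocity_t = vtr, dx = 0.2, dt_line = 0.001,
                        truth = gt, mode = "velocity")
  expect_lt(stats::median(extract_velocity(k)$value, na.rm = TRUE), 0)

  # vertical streaks: zero displacement per line
  vtr0 <- tibble::tibble(time_s = seq(0, 0.3, by = 0.01), value = rep(0, 31))
  k0 <- render_kymograph(velocity_t = vtr0, dx = 0.2, dt_line = 0.001,
                         truth = gt, mode = "velocity")
  m0 <- extract_velocity(k0)
  expect_lt(stats::median(abs(m0$value), na.rm = TRUE), 0.05)
})

test_that("velocity estimate is invariant to intensity offset and scale", {
  gt <- ground_truth(noise_sd = 0.01, seed = 4)
  vtr <- tibble::tibble(time_s = seq(0, 0.2, by = 0.01), value = rep(3, 21))
  k <- render_kymograph(velocity_t = vtr, dx = 0.2, dt_line = 0.001,
                        truth = gt, mode = "velocity")
  m0 <- extract_velocity(k)
  k2 <- k
  k2$image <- 2 * k$image + 7
  m2 <- extract_velocity(k2)
  expect_equal(m2$value, m0$value, tolerance = 1e-9)
})

test_that("activation map keeps the responding blob and is scale-invariant", {
  h <- 20; w <- 20; nf <- 30
  times <- seq(0, 29) * 0.1
  stack <- array(1, dim = c(h, w, nf))
  blob <- outer(1:h, 1:w, function(i, j) (i - 10)^2 + (j - 14)^2 <= 9)
  for (f in which(times >= 1 & times < 2))
    stack[, , f] <- stack[, , f] + blob * 2
  am <- activation_map(stack, times, stim_window = c(1, 2),
                       baseline_window = c(0, 1), threshold_frac = 0.5)
  expect_true(all(am$mask[blob]))
  expect_false(any(am$mask[!blob]))
  am2 <- activation_map(2 * stack, times, c(1, 2), c(0, 1), 0.5)
  expect_identical(am2$mask, am$mask)

  # stimulus-free stack: zero mean change, clipped score, empty mask
  am0 <- activation_map(array(1, dim = c(4, 4, 10)), seq(0, 0.9, 0.1),
                        c(0.5, 0.9), c(0, 0.5), 0.5)
  expect_false(any(am0$mask))
  expect_error(activation_map(stack, times, c(100, 101), c(0, 1), 0.5),
               "window")
})

test_that("rendering validates its inputs", {
  gt <- quiet_truth()
  dtr <- tibble::tibble(time_s = c(0, 0.1), value = c(50, 50))
  expect_error(render_kymograph(diameter_t = dtr, dx = 0.2, dt_line = 0.001,
                                truth = gt, mode = "diameter",
                                scan_len_um = 40), "exceeds")
  expect_error(kymograph(matrix(1, 2, 2), dt_line = -1, dx = 0.2), "dt_line")
})
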