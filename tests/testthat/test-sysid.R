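make_stim <- function(impulses, dt = 0.01, pixel_step = 3.75) {
  structure(list(time = (seq_along(impulses) - 1) * dt,
                 impulses = impulses, dt = dt, pixel_step = pixel_step,
                 seed = NULL), class = "velocity_stimulus")
}
make_wb <- function(dwba, dt = 0.01, condition = "water") {
  structure(list(time = (seq_along(dwba) - 1) * dt, dwba = dwba,
                 condition = condition, dt = dt), class = "wingbeat_trace")
}

test_that("cross-correlation recovers the kernel on noiseless LTI data", {
  stim <- gen_white_noise_stimulus(240, 0.01, seed = 5)
  p <- plant_params(noise_sd = 0)
  y <- simulate_steering_plant(stim, p)
  k <- estimate_impulse_response(stim, y, max_lag = 1)
  g_true <- double_exp_kernel(k$lag, p$amp, p$tau_rise, p$tau_decay)
  nrmse <- sqrt(mean((k$g - g_true)^2)) / diff(range(g_true))
  expect_lt(nrmse, 0.05)
  expect_equal(k$lag[1], 0)
  expect_equal(k$g_per_pixel, k$g * 3.75)
})

test_that("all-zero response gives an all-zero kernel", {
  stim <- make_stim(c(3.75, 0, -3.75, 3.75, rep(0, 196)))
  k <- estimate_impulse_response(stim, make_wb(numeric(200)), max_lag = 0.5)
  expect_true(all(k$g == 0))
})

test_that("a shifted copy of the stimulus yields a unit kernel at that lag", {
  n <- 400
  x <- numeric(n); x[50] <- 3.75
  shift <- 7
  y <- c(numeric(shift), x[1:(n - shift)])
  k <- estimate_impulse_response(make_stim(x), make_wb(y), max_lag = 0.2)
  expect_equal(k$g[shift + 1], 1, tolerance = 1e-12)
  expect_true(all(k$g[-(shift + 1)] == 0))
})

test_that("estimator errors on grid mismatch and zero-variance stimulus", {
  stim <- make_stim(numeric(100) + c(3.75, numeric(99)))
  expect_error(estimate_impulse_response(stim, make_wb(numeric(50))),
               "grid")
  z <- make_stim(numeric(100))
  expect_error(estimate_impulse_response(z, make_wb(numeric(100)),
                                         max_lag = 0.2), "variance")
  expect_error(estimate_impulse_response(stim, make_wb(numeric(100)),
                                         max_lag = 2), "max_lag")
})

test_that("estimator is linear in the response", {
  stim <- gen_white_noise_stimulus(20, 0.01, seed = 21)
  set.seed(77)
  y1 <- rnorm(2000); y2 <- rnorm(2000)
  est <- function(y) estimate_impulse_response(stim, make_wb(y),
                                               max_lag = 0.3)$g
  expect_equal(est(2.5 * y1 - 1.3 * y2), 2.5 * est(y1) - 1.3 * est(y2),
               tolerance = 1e-10)
})

test_that("double-exponential fit recovers exact parameters within 1%", {
  lag <- seq(0, 1, by = 0.01)
  k <- list(lag = lag, g = double_exp_kernel(lag, 1, 0.02, 0.15))
  f <- fit_double_exponential(k)
  expect_true(f$converged)
  expect_equal(f$amp, 1, tolerance = 0.01)
  expect_equal(f$tau_rise, 0.02, tolerance = 0.01)
  expect_equal(f$tau_decay, 0.15, tolerance = 0.01)
  pk <- double_exp_peak(1, 0.02, 0.15)
  expect_equal(f$peak_amplitude, pk$peak_amplitude, tolerance = 0.01)
})

test_that("scaling the kernel scales the fitted peak, taus unchanged", {
  lag <- seq(0, 1, by = 0.01)
  k1 <- list(lag = lag, g = double_exp_kernel(lag, 1, 0.02, 0.15))
  k2 <- list(lag = lag, g = 1.4 * k1$g)
  f1 <- fit_double_exponential(k1)
  f2 <- fit_double_exponential(k2)
  expect_equal(f2$peak_amplitude / f1$peak_amplitude, 1.4, tolerance = 1e-6)
  expect_equal(f2$tau_rise, f1$tau_rise, tolerance = 1e-4)
  expect_equal(f2$tau_decay, f1$tau_decay, tolerance = 1e-4)
})

test_that("fitted peak amplitude is stable across lag-grid resolutions", {
  peaks <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    lag <- seq(0, 1, by = dt)
    fit_double_exponential(
      list(lag = lag,
           g = double_exp_kernel(lag, 1, 0.02, 0.15)))$peak_amplitude
  }, numeric(1))
  expect_lt(diff(range(peaks)) / mean(peaks), 0.02)
})

test_that("kernel needs at least 10 lags", {
  lag <- seq(0, 0.08, by = 0.01)
  expect_error(fit_double_exponential(
    list(lag = lag, g = double_exp_kernel(lag))), "10 lags")
})

test_that("median peak error stays below 10% at the fixture SNR", {
  errs <- vapply(1:100, function(i) {
    r <- sysid_single_fly(plant_params(), duration = 60, seed = 3000 + i)
    true_pk <- double_exp_peak(1, 0.02, 0.15)$peak_amplitude
    abs(r$water$peak_amplitude - true_pk) / true_pk
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("per-fly percent-change estimates are nearly unbiased at default SNR", {
  pcts <- vapply(1:100, function(i) {
    r <- sysid_single_fly(plant_params(), duration = 60, seed = 8000 + i)
    100 * (r$odor$peak_amplitude - r$water$peak_amplitude) /
      r$water$peak_amplitude
  }, numeric(1))
  expect_lt(abs(mean(pcts) - 40), 5)
})

test_that("paired odor comparison handles exact and degenerate inputs", {
  w <- c(1, 1.2, 0.9, 1.1)
  r <- compare_odor_modulation(as.list(w), as.list(1.4 * w))
  expect_equal(r$percent_change, 40, tolerance = 1e-12)
  expect_lt(r$p_value, 0.05)
  same <- compare_odor_modulation(as.list(w), as.list(w))
  expect_equal(same$percent_change, 0)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_error(compare_odor_modulation(list(1), list(1)), "2 flies")
  expect_error(compare_odor_modulation(list(1, 2), list(1)), "matched")
})
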