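test_that("gaussian receptive-field fit recovers exact parameters within 1%", {
  az <- seq(-108, 108, by = 13.5)
  y <- 0 + 1 * exp(-4 * log(2) * (az - 25)^2 / 50^2)
  fit <- fit_azimuthal_rf(tibble::tibble(stimulus_value = az,
                                         mean_response = y))
  expect_true(fit$converged)
  expect_equal(fit$center, 25, tolerance = 0.01)
  expect_equal(fit$fwhm, 50, tolerance = 0.01)
  expect_equal(fit$amplitude, 1, tolerance = 0.01)
})

test_that("flat curves are flagged rather than fitted", {
  az <- seq(-100, 100, by = 25)
  fit <- fit_azimuthal_rf(tibble::tibble(stimulus_value = az,
                                         mean_response = rep(0.3, length(az))))
  expect_false(fit$converged)
  expect_error(fit_azimuthal_rf(tibble::tibble(stimulus_value = 1:3,
                                               mean_response = 1:3)),
               "azimuth samples")
})

test_that("rf fits are invariant to response rescaling", {
  cellm <- stock_cell_model("Hx")
  rf <- simulate_tuning_responses(cellm, "rf", n_flies = 7, seed = 2)
  f1 <- fit_azimuthal_rf(tuning_curve(rf))
  rf2 <- rf; rf2$peak_dff <- 5 * rf$peak_dff
  f2 <- fit_azimuthal_rf(tuning_curve(rf2))
  expect_equal(f2$center, f1$center, tolerance = 1e-6)
  expect_equal(f2$fwhm, f1$fwhm, tolerance = 1e-6)
  expect_equal(f2$amplitude, 5 * f1$amplitude, tolerance = 1e-6)
})

test_that("bar-width monotonicity statistic behaves at its extremes", {
  df <- tibble::tibble(fly_id = "f1", stimulus_value = c(5, 10, 20, 40),
                       peak_dff = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(bar_width_curve(df)$spearman_rho, 1)
  flat <- df; flat$peak_dff <- rep(0.2, 4)
  expect_equal(bar_width_curve(flat)$spearman_rho, 0)
  fx <- simulate_tuning_responses(stock_cell_model("Hx"), "width",
                                  n_flies = 7, seed = 4)
  expect_gt(bar_width_curve(fx)$spearman_rho, 0.8)
})

test_that("direction tuning normalizes to 1 and reports ties", {
  fx <- simulate_tuning_responses(stock_cell_model("Hx"), "direction",
                                  n_flies = 7, seed = 5)
  dt <- direction_tuning(fx)
  expect_equal(max(dt$curve$normalized), 1)
  expect_equal(dt$preferred, "back_to_front")
  unif <- tibble::tibble(fly_id = "f1",
                         stimulus_value = names(arena_directions()),
                         peak_dff = rep(0.5, 8))
  du <- direction_tuning(unif)
  expect_true(all(du$curve$normalized == 1))
  expect_length(du$preferred, 8)
})

test_that("direction tuning output is scale-free", {
  fx <- simulate_tuning_responses(stock_cell_model("Hx"), "direction",
                                  n_flies = 7, seed = 6)
  a <- direction_tuning(fx)
  fx$peak_dff <- fx$peak_dff * 12
  b <- direction_tuning(fx)
  expect_equal(a$curve$normalized, b$curve$normalized, tolerance = 1e-12)
  expect_identical(a$preferred, b$preferred)
})

test_that("log-gaussian temporal-frequency fit recovers an exact optimum", {
  f <- 2^seq(-2, 3, length.out = 8)
  y <- 0.1 + 0.9 * exp(-(log2(f) - log2(1))^2 / (2 * 1.2^2))
  opt <- temporal_frequency_optimum(tibble::tibble(stimulus_value = f,
                                                   mean_response = y))
  expect_equal(opt$f_opt, 1, tolerance = 0.02)
  expect_equal(opt$method, "fit")
  expect_false(opt$boundary)
})

test_that("monotone decreasing curves are flagged as boundary optima", {
  f <- 2^seq(-2, 3, length.out = 6)
  opt <- temporal_frequency_optimum(tibble::tibble(stimulus_value = f,
                                                   mean_response = rev(seq_along(f)) / 6))
  expect_true(opt$boundary)
  expect_lte(opt$f_opt, min(f) + 1e-9)
})

test_that("temporal-frequency identity converts arena speed to Hz", {
  expect_equal(temporal_frequency(22, 27), 22 / 27)
  expect_equal(temporal_frequency(22, 27), 0.815, tolerance = 0.001)
  expect_error(temporal_frequency(22, 0), "wavelength")
})
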