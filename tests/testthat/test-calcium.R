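flat_design <- epoch_design()

test_that("dF/F has the defining pointwise form", {
  t <- seq(0, 20, by = 0.1)
  f <- rep(50, length(t)); f[t >= 12] <- 100
  tr <- roi_trace(t, f)
  d <- compute_dff(tr, flat_design)
  expect_equal(d$f0, 50)
  expect_true(all(d$dff[t >= 12] == 1))
  expect_true(all(d$dff[t < 12] == 0))
  const <- compute_dff(roi_trace(t, rep(7, length(t))), flat_design)
  expect_true(all(const$dff == 0))
})

test_that("dF/F is invariant to multiplicative gain on F", {
  tr <- simulate_roi_trace(stock_cell_model("Hx"), seed = 3)
  tr2 <- tr; tr2$F <- 3.7 * tr$F
  expect_equal(compute_dff(tr)$dff, compute_dff(tr2)$dff, tolerance = 1e-12)
})

test_that("dF/F guards its baseline window", {
  t <- seq(0, 20, by = 0.1)
  tr <- roi_trace(t, rep(10, length(t)))
  expect_error(compute_dff(tr, baseline_window = c(5, 5.1)), "3 frames")
})

test_that("epoch peaks localize responses to the correct epoch", {
  t <- seq(0, 109.9, by = 0.1)
  dff <- numeric(length(t))
  d <- structure(list(time = t, dff = dff, f0 = 100, fly_id = "f",
                      dt = 0.1), class = "dff_trace")
  expect_equal(epoch_peaks(d, flat_design)$peaks, rep(0, 5))
  win <- epoch_windows(flat_design)
  dff[which.min(abs(t - (win$epochs[3, 1] + 4)))] <- 0.8
  d$dff <- dff
  expect_equal(epoch_peaks(d, flat_design)$peaks, c(0, 0, 0.8, 0, 0))
})

test_that("epoch peaks follow a permutation of the epoch windows", {
  t <- seq(0, 109.9, by = 0.1)
  win <- epoch_windows(flat_design)
  vals <- c(0.5, 0.1, 0.9, 0.3, 0.7)
  dff <- numeric(length(t))
  for (k in 1:5) dff[t >= win$epochs[k, 1] & t < win$epochs[k, 2]] <- vals[k]
  d <- structure(list(time = t, dff = dff, f0 = 1, fly_id = "f", dt = 0.1),
                 class = "dff_trace")
  pk <- epoch_peaks(d, flat_design, lag_pad = 0)$peaks
  expect_equal(pk, vals)
})

test_that("all flies show the epoch-2 enhancement at the fixture noise level", {
  traces <- simulate_imaging_cohort(stock_cell_model("Hx"), n_flies = 13,
                                    seed = 50)
  peaks <- t(vapply(traces, function(tr)
    epoch_peaks(compute_dff(tr))$peaks, numeric(5)))
  expect_true(all(peaks[, 2] > peaks[, 1]))
})

test_that("rank-sum statistic matches the brute-force pair-count oracle", {
  traces <- simulate_imaging_cohort(stock_cell_model("Hx"), n_flies = 13,
                                    seed = 50)
  resp <- lapply(traces, function(tr) epoch_peaks(compute_dff(tr)))
  stats <- odor_modulation_test(resp)
  w2 <- stats$tests$w_statistic[stats$tests$epoch == 2]
  expect_equal(w2, oracle_ranksum_W(stats$peaks[, 2], stats$peaks[, 1]))
  # fully separated 13-vs-13 attains the enumerated extreme value 13 * 13
  expect_equal(w2, 169)
  expect_lt(stats$tests$p_value[stats$tests$epoch == 2], 0.05)
})

test_that("identical epochs give p = 1 for every comparison", {
  r <- lapply(1:5, function(i)
    structure(list(peaks = rep(0.4, 5), fly_id = paste0("f", i)),
              class = "epoch_response"))
  stats <- odor_modulation_test(r)
  expect_true(all(stats$tests$p_value == 1))
})

test_that("odor on/off comparison flags degenerate and detects real responses", {
  t <- seq(0, 109.9, by = 0.1)
  mk <- function(on_amp, id) {
    dff <- numeric(length(t))
    dff[t >= 30 & t < 40] <- on_amp
    structure(list(time = t, dff = dff, f0 = 1, fly_id = id, dt = 0.1),
              class = "dff_trace")
  }
  same <- lapply(1:4, function(i) mk(0, paste0("f", i)))
  r0 <- odor_on_off_test(same, c(30, 40), c(20, 30))
  expect_true(r0$degenerate)
  expect_equal(r0$p_value, 1)
  set.seed(31)
  resp <- lapply(1:6, function(i) mk(0.5 + runif(1, 0, 0.3), paste0("f", i)))
  r1 <- odor_on_off_test(resp, c(30, 40), c(20, 30))
  expect_true(all(r1$per_fly$on > r1$per_fly$off))
  expect_lt(r1$p_value, 0.005)
  # mis-placed off window inside the pulse sees no difference
  r2 <- odor_on_off_test(resp, c(30, 35), c(35, 40))
  expect_true(r2$degenerate || r2$p_value > 0.05)
})

test_that("Tdc2 fixture responds to odor in every fly", {
  traces <- simulate_imaging_cohort(stock_cell_model("Tdc2"), n_flies = 6,
                                    stimulus_params = list(kind = "none"),
                                    seed = 12)
  dffs <- lapply(traces, compute_dff)
  r <- odor_on_off_test(dffs, c(30, 40), c(20, 30))
  expect_true(all(r$per_fly$on > r$per_fly$off))
  expect_lt(r$p_value, 0.005)
})

test_that("qc filter separates clean, bleaching and unresponsive traces", {
  clean <- simulate_roi_trace(stock_cell_model("Hx"), seed = 2)
  t <- clean$time
  bleach <- roi_trace(t, 100 * pmax(1 - 0.5 * t / 60, 0.02),
                      roi_id = "bleach")
  set.seed(6)
  flat <- roi_trace(t, 100 + rnorm(length(t), 0, 3), roi_id = "flat")
  res <- qc_filter(list(clean, bleach, flat))
  expect_equal(res$report$included, c(TRUE, FALSE, FALSE))
  expect_match(res$report$reasons[2], "bleaching")
  expect_match(res$report$reasons[3], "responsiveness")
})

test_that("qc movement rule catches jump-ridden traces", {
  t <- seq(0, 109.9, by = 0.1)
  set.seed(13)
  f <- 100 * exp(rnorm(length(t), 0, 0.6))
  res <- qc_filter(list(roi_trace(t, f, roi_id = "jumpy")))
  expect_match(res$report$reasons[1], "movement")
})

test_that("null cohorts keep the family-wise false-enhancement rate within bounds", {
  # with no odor gain, the fraction of cohorts with any significant epoch
  # stays below the Bonferroni family-wise bound (4 x 0.05) plus MC slack;
  # the rank-sum applied to within-fly-paired peaks is conservative
  any_sig <- vapply(1:60, function(i) {
    t <- water_null_cohort(seed = 90000 + i)
    any(t$p_value < 0.05)
  }, logical(1))
  expect_lte(mean(any_sig), 0.2)
})
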