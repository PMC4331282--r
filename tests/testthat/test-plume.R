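test_that("angular distance follows circular geometry", {
  expect_equal(angular_distance(180, 180), 0)
  expect_equal(angular_distance(350, 10), 20)
  expect_equal(angular_distance(0, 180), 180)
  expect_equal(angular_distance(c(90, 270), 180), c(90, 90))
})

test_that("noise-free fly starting on the plume stays on it", {
  prof <- agent_profile(heading_noise_sd = 0)
  tr <- simulate_plume_flight(prof, plume_azimuth = 180, duration = 5,
                              dt = 0.02, seed = 1, theta0 = 180)
  expect_true(all(abs(tr$heading - 180) < 1e-9))
})

test_that("headings stay wrapped and runs are reproducible", {
  prof <- stock_profile("control")
  tr1 <- simulate_plume_flight(prof, seed = 42)
  tr2 <- simulate_plume_flight(prof, seed = 42)
  expect_identical(tr1$heading, tr2$heading)
  expect_true(all(tr1$heading >= 0 & tr1$heading < 360))
})

test_that("detection requires a contiguous dwell, matching the scan oracle", {
  expect_true(detect_plume(make_heading(rep(180, 50))))
  expect_false(detect_plume(make_heading(rep(0, 50), plume = 180)))
  # single in-cone sample at dt = 0.1 s is below the 0.5 s dwell
  h <- rep(90, 50); h[20] <- 180
  tr <- make_heading(h, dt = 0.1)
  expect_false(detect_plume(tr, min_dwell = 0.5))
  expect_lt(oracle_max_dwell(angular_distance(h, 180) <= 10, 0.1), 0.5)
  # five contiguous samples reach exactly 0.5 s
  h2 <- rep(90, 50); h2[20:24] <- 180
  expect_true(detect_plume(make_heading(h2, dt = 0.1), min_dwell = 0.5))
})

test_that("time in plume counts samples like the direct oracle", {
  tr <- make_heading(rep(180, 100), dt = 0.1)
  expect_equal(time_in_plume(tr, c(0, 10)), 10)
  expect_equal(time_in_plume(make_heading(rep(0, 100), dt = 0.1),
                             c(0, 10)), 0)
  alt <- rep(c(180, 90), 50)
  tra <- make_heading(alt, dt = 0.1)
  inside <- angular_distance(alt, 180) <= 10
  expect_equal(time_in_plume(tra, c(0, 10)),
               oracle_time_in(tra$time, inside, 0, 10, 0.1))
  expect_equal(abs(time_in_plume(tra, c(0, 10)) - 5) <= 0.1, TRUE)
})

test_that("time in plume is additive over disjoint windows and monotone in threshold", {
  set.seed(8)
  h <- runif(400, 0, 360)
  tr <- make_heading(h, dt = 0.1)
  expect_equal(time_in_plume(tr, c(0, 20)) + time_in_plume(tr, c(20, 40)),
               time_in_plume(tr, c(0, 40)))
  ts <- vapply(c(5, 10, 20, 45, 90, 180), function(th)
    time_in_plume(tr, c(0, 40), threshold = th), numeric(1))
  expect_true(all(diff(ts) >= 0))
})

test_that("metrics are invariant to un-wrapped heading input", {
  set.seed(9)
  h <- runif(300, 0, 360)
  tr1 <- make_heading(h, dt = 0.1)
  tr2 <- make_heading(h + 360 * sample(-3:3, 300, TRUE), dt = 0.1)
  expect_equal(plume_metrics(tr1)[-1], plume_metrics(tr2)[-1])
})

test_that("control flies detect the plume in at least 70% of 25 seeded runs", {
  prof <- stock_profile("control")
  det <- vapply(1:25, function(s)
    detect_plume(simulate_plume_flight(prof, seed = s)), logical(1))
  expect_gte(mean(det), 0.70)
})

test_that("hand-counted 2x2 detection chi-square value is reproduced", {
  mk <- function(on, n, g) lapply(seq_len(n), function(i)
    make_heading(rep(if (on) 180 else 0, 60), fly = paste0(g, i), group = g))
  traces <- c(mk(TRUE, 10, "A"), mk(FALSE, 10, "B"))
  cmp <- summarize_plume_tracking(traces)
  expect_equal(cmp$group_summary$detection_prop, c(1, 0))
  expect_equal(cmp$detection_test$statistic, 20, tolerance = 1e-12)
})

test_that("identical groups give chi-square p = 1 and identical means", {
  mk <- function(g) lapply(1:6, function(i) {
    h <- c(rep(180, 30), rep(0, 30))
    make_heading(h, dt = 0.5, fly = paste0(g, i), group = g)
  })
  cmp <- summarize_plume_tracking(c(mk("A"), mk("B")))
  expect_equal(cmp$detection_test$p_value, 1)
  gs <- cmp$group_summary
  expect_equal(gs$acquisition_mean[1], gs$acquisition_mean[2])
  expect_equal(gs$tracking_mean[1], gs$tracking_mean[2])
})

test_that("a single group summarizes without pairwise tests", {
  traces <- lapply(1:4, function(i)
    make_heading(rep(180, 60), fly = paste0("f", i), group = "only"))
  cmp <- summarize_plume_tracking(traces)
  expect_null(cmp$pairwise)
  expect_null(cmp$detection_test)
  expect_equal(nrow(cmp$group_summary), 1)
})

test_that("loss of stabilization breaks tracking but not acquisition", {
  ctl <- stock_profile("control")
  def <- stock_profile("T4T5_blocked")
  traces <- c(lapply(1:25, function(s)
                simulate_plume_flight(ctl, seed = 100 + s)),
              lapply(1:25, function(s)
                simulate_plume_flight(def, seed = 600 + s)))
  cmp <- summarize_plume_tracking(traces)
  pw <- cmp$pairwise
  expect_lt(pw$p_value[pw$metric == "tracking_s"], 0.05)
  expect_gt(pw$p_value[pw$metric == "acquisition_s"], 0.05)
})
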