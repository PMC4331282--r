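# Simulate one water-vapor-control imaging cohort (no odor gain) and return
# the epoch-wise rank-sum results.
water_null_cohort <- function(seed, n_flies = 6) {
  cellm <- cell_model("Hx", odor_gain = 1)
  traces <- simulate_imaging_cohort(cellm, n_flies = n_flies, seed = seed)
  resp <- lapply(traces, function(tr) epoch_peaks(compute_dff(tr)))
  odor_modulation_test(resp)$tests
}

# A cohort "shows enhancement" at epoch 2 when the two-sided rank-sum test is
# significant and the epoch-2 median exceeds the epoch-1 median.
cohort_enhanced <- function(tests, epoch = 2, alpha = 0.05) {
  row <- tests[tests$epoch == epoch, ]
  row$p_value < alpha && row$enhanced
}
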