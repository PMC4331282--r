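#!/usr/bin/env Rscript
# Rigid-tether white-noise system identification: how much does an appetitive
# odor raise the gain of the optomotor steering response?
#
# Simulates 15 flies with paired water/odor trials, estimates each yaw
# impulse response by cross-correlation, fits the double-exponential kernel,
# and compares fitted peak amplitudes within fly.

suppressPackageStartupMessages(library(odorgaze))

seed <- 1L
bundle <- run_experiment(scenario_config("rigid_odor", seed = seed),
                         out_dir = "results/01_rigid_tether")

mod <- bundle$stats$odor_modulation
message(sprintf(
  "Odor raises the fitted kernel peak by %+.1f%% across n = %d flies (paired t = %.2f, p = %.2g).",
  mod$percent_change, mod$n_flies, mod$t_statistic, mod$p_value))
message("Per-fly kernel fits written to results/01_rigid_tether/kernel_fits.csv")
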