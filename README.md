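# odorgaze

Analyses of olfactory modulation of motion vision in *Drosophila*: how an
appetitive odor changes the gain of visually guided flight, and how that
change is expressed in identified visual neurons. The package provides,
as tested reusable code plus seeded synthetic-data generators for each
experiment type:

- **White-noise system identification** of the yaw optomotor steering
  response from rigid-tether recordings: the impulse response `g(t)` is
  estimated by cross-correlating the pixel-step stimulus `x(t)` with the
  wingbeat-difference signal `y(t)` (ΔWBA),
  `g(τ) = Σ x(t) y(t+τ) / Σ x(t)²`, then fit with a double exponential
  `A (e^{-t/τ_d} − e^{-t/τ_r})`; odor-evoked gain change is the percent
  change of fitted peak amplitudes, paired within fly.
- **Plume-tracking metrics** from magnetic-tether heading traces, split into
  the three phases of the behavior: detection (ever dwelling within ±10° of
  the odor nozzle), acquisition (time in plume, first 10 s), continuous
  tracking (time in plume, final 10 s), with chi-square detection tests and
  Welch group comparisons.
- **Calcium-imaging epoch analyses**: ΔF/F extraction, per-epoch peak
  responses under the five-epoch odor-pairing protocol, rank-sum epoch
  statistics, paired odor-on/off tests, and protocol-style QC exclusion
  (movement / bleaching / responsiveness).
- **Visual tuning fits**: Gaussian azimuthal receptive field (FWHM),
  saturating bar-width curves with a Spearman monotonicity statistic,
  max-normalized direction tuning, and a log-Gaussian temporal-frequency
  optimum.

The generative models (an LTI steering plant with multiplicative odor gain;
circular heading dynamics with separable odor-attraction and
visual-stabilization terms; tuned visual drive convolved with an indicator
kernel) are documented in `vignettes/odorgaze-methods.Rmd`.

## Worked example

Simulate a 15-fly rigid-tether cohort with paired water/odor trials and run
the full identification pipeline:

```r
library(odorgaze)
bundle <- run_experiment(scenario_config("rigid_odor", seed = 1))
bundle$stats$odor_modulation
#> $percent_change
#> [1] 36.49247
#> $t_statistic
#> [1] 18.74287
#> $p_value
#> [1] 2.592159e-11
#> $n_flies
#> [1] 15
```

The cohort was generated with a 40% odor gain on the steering-plant kernel;
the pipeline (cross-correlation → double-exponential fit → paired peak
comparison) recovers a `percent_change` of about 36.5% from this seed's
noisy traces, significant by the paired t-test. `bundle$tables$kernel_fits`
holds the per-fly fitted parameters (`amp`, `tau_rise`, `tau_decay`,
`peak_amplitude`, ...).

The numbered scripts under `analysis/` run each of the study's analyses in
order and write their tables under `results/`:

```sh
Rscript analysis/01_rigid_tether_sysid.R   # odor gain on the optomotor kernel
Rscript analysis/02_plume_tracking.R       # detection/acquisition/tracking by genotype
Rscript analysis/03_hx_tuning.R            # RF width, bar width, direction, TF optimum
Rscript analysis/04_odor_pairing_imaging.R # epoch-2 enhancement and its null controls
Rscript analysis/05_octopamine.R           # Tdc2 odor response; VMAT-rescue behavior
```

For instance, `02_plume_tracking.R` prints per-genotype summaries such as
`T4T5_blocked n=25 detect 100% acquisition 6.4 +/- 0.6 s tracking 4.7 +/- 0.9 s`
against controls tracking ~10 s: visual-motion-blocked flies still find and
initially hold the plume but cannot sustain tracking.

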