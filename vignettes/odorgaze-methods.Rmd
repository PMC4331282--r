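---
title: "Models and methods behind odorgaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind odorgaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorgaze)
```

`odorgaze` re-implements, as a tested pipeline, three families of analyses
used to study how an appetitive odor modulates visually guided flight in
*Drosophila*: white-noise system identification of the optomotor steering
response, three-phase odor plume-tracking metrics, and epoch-structured
calcium-imaging statistics with visual tuning fits. Because the raw
recordings behind those experiments are not publicly deposited, the package
carries first-class synthetic-data generators that emulate each experiment
type; every analysis is exercised end to end against data whose ground truth
is known. This vignette documents the models, their parameters, the design
choices that were genuinely open, and what the synthetic fixtures do and do
not establish about real recordings.

## 1. The rigid-tether steering plant and its identification

### Forward model

The fly's yaw steering plant is modelled as a causal linear time-invariant
system. The stimulus `x(t)` is a ternary pixel-step sequence: at each 10 ms
frame the panorama steps one pixel (3.75°) left, right, or not at all, each
with probability 1/3. An i.i.d. ternary sequence has zero mean and a flat
spectrum up to Nyquist, which is what the cross-correlation estimator
requires. The wingbeat output is

    y(t) = (g * x)(t) + e(t),     g(t) = A (exp(-t/tau_d) - exp(-t/tau_r)),

with additive white Gaussian noise `e`. The difference-of-exponentials
kernel rises with `tau_r` and decays with `tau_d > tau_r`; its closed-form
peak sits at `t* = tau_d tau_r / (tau_d - tau_r) * log(tau_d / tau_r)`. On
odor trials the amplitude `A` is multiplied by `odor_gain`, default 1.4 — a
40% gain increase, the effect size the behavioral experiment reports. The
time constants (`tau_r` = 20 ms, `tau_d` = 150 ms) are fixture conventions
chosen to give a plausibly fast biphasic optomotor kernel; no claim about
the true fly values is attached to them.

The noise level deserves a note because it sets every downstream tolerance.
The cross-correlation estimate `g_hat(tau) = sum x(t) y(t+tau) / sum x(t)^2`
has per-lag standard error `sigma / sqrt(sum x^2)`. For the default 60 s
record at 100 Hz with 3.75° steps, `noise_sd = 30` ΔWBA a.u. puts the
kernel-estimate peak at a signal-to-noise ratio of about 5 — a deliberately
hard but workable regime: per-trace output SNR is well below 1, and the
identification succeeds only through the averaging implicit in the
cross-correlation, as in the real experiment.

### Estimator and fit

The estimator normalizes by stimulus power, so the kernel is in response
units per degree of displacement (`g_per_pixel` rescales to the 3.75° pixel
step). Lags use full overlap only — the sums run over `t <= N - L` — to
avoid circular-correlation artifacts. The double-exponential fit profiles
the amplitude out analytically (it enters linearly) and searches over
`(log tau_r, log(tau_d - tau_r))`, which enforces positivity and the
ordering `tau_d > tau_r` by construction; Nelder-Mead is restarted from a
fixed grid of 7 starting points and the lowest-RSS solution kept. Peak
amplitude and peak time are evaluated on the fitted curve in closed form,
not read off the noisy kernel samples. Per-fly odor modulation is the
percent change of mean fitted peaks, tested with a two-tailed paired t-test.

With these defaults, a 15-fly simulated cohort recovers the programmed 40%
gain change to within a few percentage points (the acceptance script
recomputes this; across seeds the estimate typically lands between 36% and
44%), and 100 single-fly replicates put the median fitted-peak error under
10% with percent-change bias under 5 points — both asserted in the test
suite.

## 2. Plume tracking on the magnetic tether

### Heading dynamics

Headings evolve in discrete time (`dt` = 20 ms, 40 s trials, plume at 180°):

    dtheta = dt * [ k_a e(t) 1(|e| <= 90°)  +  omega_s 1(|e| > 90°)  +  b(t) ]
    db     = -k_s b dt + sigma sqrt(dt) dW

where `e(t)` is the signed shortest arc to the plume. Odor sensing is binary
within a 90° half-width cone: inside it, attraction (`k_a`, 1/s) pulls the
heading toward the plume; outside it the fly performs a slow searching
rotation (`omega_s` = 25°/s, direction drawn per trial), a stand-in for the
casting and circling of real tethered flies that guarantees plume encounters
from arbitrary initial headings. The drift bias `b` is an
Ornstein-Uhlenbeck angular velocity damped at the *visual stabilization*
rate `k_s`: with `k_s > 0` the bias is bounded and the fly holds the plume;
with `k_s = 0` the bias random-walks, so heading error accumulates and the
fly progressively falls out of the plume even though its odor attraction is
untouched. This is the mechanistic reading of the behavioral result the
pipeline is built to quantify: motion signals are dispensable for finding
the plume but required to stay in it.

Defaults (`k_a` = 2.0/s, `k_s` = 1.5/s, `sigma` = 4.5 °/s/sqrt(s)) were
calibrated once, before any test was frozen, to place the control genotype
in the regime the study describes: essentially complete detection, most of
the final 10 s spent inside the ±10° plume cone, and — for the
stabilization-less profile — acquisition statistically indistinguishable
from control while sustained tracking collapses. The reduced-attraction
mutant profile (`k_a` = 0.15/s, stabilization intact) emulates the
monoamine-transport mutant, whose total plume residence falls toward the
water-control level.

### Metrics

Detection requires a contiguous dwell of at least 0.5 s within ±10° of the
plume azimuth — a single-sample crossing does not count, which avoids
scoring saccadic fly-throughs as detections. Acquisition and tracking are
time-in-plume over the half-open windows [0, 10) s and [T-10, T) s;
non-detecting flies are excluded before any time metric is computed.
Detection proportions are compared across groups by chi-square without
continuity correction (a degenerate table — all groups at 100% or 0% — is
reported as statistic 0, p = 1 rather than NaN). Between-genotype time
comparisons use unpaired two-tailed Welch t-tests: pairing across different
animals is not possible, so the paired test named in some figure legends is
interpreted as its unpaired analogue; paired variants remain available
where shapes genuinely match (within-fly odor on/off windows).

## 3. Calcium imaging: ΔF/F, epochs, and nulls

### Trace synthesis

A cell's visual drive is the product of three weights: a Gaussian azimuthal
receptive field (FWHM 50°, centered 25° ipsilateral of midline), a von Mises
direction weight over the 8 arena directions (back-to-front over the
ipsilateral eye is the preferred reference; the study's own text is
internally inconsistent about front-to-back vs back-to-front for the
full-field grating, and the package fixes back-to-front, consistent with
the cell's lobula-plate layer-2 innervation), and a log-Gaussian
temporal-frequency weight peaking at 1 Hz with 1.5-octave width. The
bar-width response is obtained by integrating the receptive-field profile
over the bar extent, which yields the observed saturating growth with bar
width without any extra free parameter. Drive is scaled by `odor_gain`
during the odor window (Hx 1.2; exactly 1.0 for T4T5 and HSE, enforced by
the constructor) and a direct, vision-independent odor drive models the
octopaminergic Tdc2 terminals. The drive is low-pass filtered by a unit-DC
single-exponential indicator kernel (decay 0.6 s; rise time neglected) and
embedded as `F = F0 (1 + c) + noise`, floored just above zero so traces are
strictly positive. Frames run at 10 Hz, within the acquisition range of the
instrument being emulated.

The epoch schedule is the five-epoch pairing protocol: 10 s initial rest,
then five 10-s motion epochs separated by 10-s rests, with a 10-s odor
pulse concurrent with the second motion epoch. Because 10 s is ~17 indicator
time constants, the filtered drive reaches steady state within each epoch,
so a noiseless Hx trace has an epoch-2 : epoch-1 peak ratio of exactly
`odor_gain` — a construction identity the tests assert.

### Statistics

ΔF/F uses `F0` = mean fluorescence over the final 5 s of the initial rest
(the rolling-percentile alternative was considered and rejected for the
fixtures: with a known flat baseline the rest-mean is unbiased and simpler).
Per-epoch peaks are maxima over the epoch window plus a 2 s lag pad for
indicator-delayed peaks. Epoch 1 is compared to each later epoch by the
Wilcoxon rank-sum test, exactly as the protocol states, with the signed-rank
variant reported alongside (the peaks are within-fly paired, so rank-sum is
conservative here; both are exposed). "Significant epoch-2 enhancement" is
defined as two-sided rank-sum p < 0.05 *and* epoch-2 median above epoch-1
median. Under the water-vapor null (odor gain 1), simulated 6-fly cohorts
show such enhancement in only a few percent of runs — the test suite
requires at least 95 of 100 null cohorts clean, and observes ~98. The
family-wise false-positive rate across the four epoch comparisons stays
well under the Bonferroni bound, reflecting both test discreteness at n = 6
and the within-fly coupling of epoch peaks through the shared baseline.

### Quality control

Three exclusion rules mirror the experimental protocol, each with a reason
code: movement (more than 5% of frames with frame-to-frame |ΔF|/F above
0.5), bleaching (fitted linear drift below -20%/min), and responsiveness
(fewer than 2 epochs with peak above 2 baseline noise SDs). The numeric
cutoffs are package conventions — the protocol states the rules, not the
numbers — and are echoed in every QC report. For the responsiveness rule
the peak is taken on a 0.5 s running mean: the raw maximum of ~100 noise
frames exceeds 2 SD by extreme-value statistics alone, so an unsmoothed
rule would pass flat traces.

## 4. Tuning fits

The azimuthal receptive field is fit as a Gaussian parameterized directly by
FWHM (`response = baseline + amplitude * exp(-4 ln2 (az-center)^2 / fwhm^2)`);
"receptive-field width" in this package always means Gaussian FWHM. The
temporal-frequency optimum comes from a log-Gaussian in `log2 f`, with a
fallback to the sampled argmax (flagged as a boundary case) when the fit
fails or the optimum escapes the sampled range. Both fits use
Levenberg-Marquardt with data-driven starts; a flat curve is flagged as
unidentifiable rather than fitted. All fits are invariant to multiplicative
rescaling of the responses, and direction tuning is normalized to its
maximum (exact ties report all maximizers), making it fully scale-free.
A helper converts grating speed to temporal frequency (`tf = v / lambda`;
the arena's 22°/s over a 27° wavelength is 0.815 Hz).

## 5. Reproducibility, problem sizes, and limitations

Every generator takes an explicit seed, restores the caller's RNG state,
and derives per-fly sub-seeds within the 32-bit range; identical
configuration plus seed reproduces every table byte for byte (asserted in
the tests, and every results bundle embeds its config hash). The default
problem sizes — 60 s identification records, 15-fly rigid-tether cohorts,
25-per-group 40 s plume trials, 100-cohort null simulations — are the
study's own cohort sizes where stated, and otherwise chosen so that each
analysis stage has the statistical resolution its claims need while a full
run of the suite stays interactive.

What the synthetic fixtures do **not** establish: the steering plant of real
flies is neither perfectly linear nor time-invariant (habituation, arousal
drift); real heading traces contain saccades and spontaneous turns rather
than smooth OU drift; real calcium traces have shot noise scaling with
brightness, motion artifacts, and indicator nonlinearity, none of which are
modelled beyond the QC rules that would exclude their extremes. Passing the
suite therefore demonstrates that the *analysis pipeline* is correct and
well-calibrated — that it recovers known gains, widths, optima, and group
differences from data with the assumed statistical structure — not that the
biological parameter values themselves are as the defaults state. HDF5 trace
containers are not provided; the tidy CSV + JSON-sidecar format is the
interchange representation throughout.
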