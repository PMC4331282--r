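#' Steering-plant parameters for the rigid-tether simulator
#'
#' Parameter set for the linear time-invariant steering plant used to emulate
#' rigid-tether optomotor recordings. The impulse response is the difference of
#' two exponentials, `g(t) = amp * (exp(-t/tau_decay) - exp(-t/tau_rise))`,
#' which rises with time constant `tau_rise` and decays with `tau_decay`.
#' On odor trials the kernel amplitude is multiplied by `odor_gain`.
#'
#' @param amp Kernel amplitude in dWBA a.u. per degree of pattern displacement.
#' @param tau_rise Rise time constant in seconds (> 0).
#' @param tau_decay Decay time constant in seconds (> `tau_rise`).
#' @param odor_gain Dimensionless multiplicative gain applied to `amp` on odor
#'   trials (>= 0). Default 1.4, i.e. a 40% odor-evoked increase in the
#'   optomotor response.
#' @param noise_sd Standard deviation of additive Gaussian noise on the dWBA
#'   trace, in dWBA a.u. The default (30) puts the peak of the
#'   cross-correlation kernel estimate at a signal-to-noise ratio of about 5
#'   for a 60 s record sampled at 100 Hz.
#'
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(amp = 1, tau_rise = 0.02, tau_decay = 0.15,
                         odor_gain = 1.4, noise_sd = 30) {
  if (!is.numeric(tau_rise) || tau_rise <= 0)
    stop_invalid("tau_rise must be > 0")
  if (!is.numeric(tau_decay) || tau_decay <= tau_rise)
    stop_invalid("tau_decay must exceed tau_rise")
  if (!is.numeric(odor_gain) || odor_gain < 0)
    stop_invalid("odor_gain must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_invalid("noise_sd must be >= 0")
  structure(list(amp = amp, tau_rise = tau_rise, tau_decay = tau_decay,
                 odor_gain = odor_gain, noise_sd = noise_sd),
            class = "plant_params")
}

#' Difference-of-exponentials impulse-response kernel
#'
#' Evaluates `g(t) = amp * (exp(-t/tau_decay) - exp(-t/tau_rise))`, the causal
#' steering-plant kernel; zero for `t < 0`.
#'
#' @param t Lag times in seconds (vector).
#' @param amp,tau_rise,tau_decay Kernel parameters (see [plant_params()]).
#' @return Numeric vector of kernel values.
#' @export
double_exp_kernel <- function(t, amp = 1, tau_rise = 0.02, tau_decay = 0.15) {
  ifelse(t < 0, 0, amp * (exp(-t / tau_decay) - exp(-t / tau_rise)))
}

#' Peak lag and amplitude of a difference-of-exponentials kernel
#'
#' Closed-form maximum of `amp * (exp(-t/tau_decay) - exp(-t/tau_rise))` over
#' `t >= 0`: the peak sits at
#' `t* = tau_decay*tau_rise/(tau_decay - tau_rise) * log(tau_decay/tau_rise)`.
#'
#' @inheritParams double_exp_kernel
#' @return List with `peak_time` (s) and `peak_amplitude`.
#' @export
double_exp_peak <- function(amp, tau_rise, tau_decay) {
  tstar <- tau_decay * tau_rise / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  list(peak_time = tstar,
       peak_amplitude = double_exp_kernel(tstar, amp, tau_rise, tau_decay))
}

#' Generate a broadband velocity-impulse stimulus
#'
#' Emulates the white-noise stimulus of the rigid-tether experiment: at each
#' display frame the panorama either steps one pixel (3.75 degrees) clockwise,
#' one pixel counter-clockwise, or stays put, each with probability 1/3,
#' independently across frames. The resulting displacement sequence has zero
#' mean and a flat power spectrum up to the Nyquist frequency.
#'
#' @param duration Record length in seconds (> 0).
#' @param dt Sample interval in seconds (> 0).
#' @param pixel_step Display pixel size in degrees (> 0; the arena's 3.75).
#' @param seed Integer seed for reproducibility (optional).
#'
#' @return An object of class `velocity_stimulus`: list with `time` (s),
#'   `impulses` (signed displacement per sample, degrees), `dt`, `pixel_step`.
#' @export
gen_white_noise_stimulus <- function(duration, dt, pixel_step = 3.75,
                                     seed = NULL) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop_invalid("duration must be a positive number")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop_invalid("dt must be a positive number")
  if (!is.numeric(pixel_step) || pixel_step <= 0)
    stop_invalid("pixel_step must be > 0")
  n <- max(1L, as.integer(round(duration / dt)))
  steps <- with_seed(seed, sample(c(-1L, 0L, 1L), n, replace = TRUE))
  structure(list(time = (seq_len(n) - 1) * dt,
                 impulses = as.numeric(steps) * pixel_step,
                 dt = dt, pixel_step = pixel_step, seed = seed),
            class = "velocity_stimulus")
}

#' Simulate a rigid-tether wingbeat response
#'
#' Drives the linear steering plant with a velocity-impulse stimulus:
#' `y(t) = (g * x)(t) + noise`, with the causal kernel of [plant_params()].
#' On odor trials the kernel amplitude is scaled by the plant's `odor_gain`.
#' The discrete convolution uses the kernel sampled on the stimulus grid, so a
#' noiseless unit impulse in `x` reproduces `g` sample for sample.
#'
#' @param stimulus A `velocity_stimulus`.
#' @param plant A `plant_params` object.
#' @param odor_on Logical; if `TRUE` the kernel amplitude is `amp * odor_gain`.
#' @param seed Integer seed for the noise (optional).
#' @param kernel_support Length of the sampled kernel in seconds (default 1;
#'   the kernel is numerically negligible beyond that).
#'
#' @return An object of class `wingbeat_trace`: list with `time`, `dwba`,
#'   `condition` ("odor" or "water"), `dt`.
#' @export
simulate_steering_plant <- function(stimulus, plant = plant_params(),
                                    odor_on = FALSE, seed = NULL,
                                    kernel_support = 1) {
  stopifnot(inherits(stimulus, "velocity_stimulus"),
            inherits(plant, "plant_params"))
  dt <- stimulus$dt
  amp <- plant$amp * if (odor_on) plant$odor_gain else 1
  lags <- seq(0, kernel_support, by = dt)
  g <- double_exp_kernel(lags, amp, plant$tau_rise, plant$tau_decay)
  x <- stimulus$impulses
  n <- length(x)
  k <- length(g)
  y <- stats::filter(c(rep(0, k - 1), x), g, method = "convolution",
                     sides = 1)
  y <- as.numeric(y)[k:(n + k - 1)]
  if (plant$noise_sd > 0)
    y <- y + with_seed(seed, rnorm(n, 0, plant$noise_sd))
  structure(list(time = stimulus$time, dwba = y,
                 condition = if (odor_on) "odor" else "water", dt = dt),
            class = "wingbeat_trace")
}
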