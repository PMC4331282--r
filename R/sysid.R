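#' Estimate the yaw optomotor impulse response by cross-correlation
#'
#' White-noise system identification of the fly's steering plant: the kernel
#' estimate at lag `tau` is `g(tau) = sum_t x(t) y(t+tau) / sum_t x(t)^2`.
#' Because the stimulus impulses are (near) white, this recovers the impulse
#' response of the linear plant mapping pattern displacement to dWBA. Lags are
#' computed only where the full overlap exists (no circular correlation): the
#' sums run over `t = 1 .. N - L` where `L` is the number of lag samples.
#'
#' The returned `g` is the response per unit of `x` (per degree of pattern
#' displacement when `x` is in degrees); `g_per_pixel` rescales it to the
#' response to a one-pixel (`pixel_step`, 3.75 degree) displacement step.
#'
#' @param stimulus A `velocity_stimulus` (the `x(t)` sequence).
#' @param trace A `wingbeat_trace` on the same sample grid (the `y(t)` signal).
#' @param max_lag Maximum kernel lag in seconds (default 1; must be shorter
#'   than the record).
#'
#' @return An object of class `impulse_kernel`: list with `lag` (s, from 0),
#'   `g` (response per unit impulse), `g_per_pixel`, `dt`, `pixel_step`,
#'   `condition`.
#' @export
estimate_impulse_response <- function(stimulus, trace, max_lag = 1) {
  stopifnot(inherits(stimulus, "velocity_stimulus"),
            inherits(trace, "wingbeat_trace"))
  x <- stimulus$impulses
  y <- trace$dwba
  if (length(x) != length(y) ||
      !isTRUE(all.equal(stimulus$dt, trace$dt)))
    stop_invalid("stimulus and trace must share one sample grid")
  dt <- stimulus$dt
  n <- length(x)
  L <- as.integer(round(max_lag / dt))
  if (L >= n) stop_invalid("max_lag must be shorter than the record")
  idx <- seq_len(n - L)
  xs <- x[idx]
  denom <- sum(xs^2)
  if (denom == 0) stop_invalid("stimulus has zero variance over the record")
  g <- vapply(0:L, function(k) sum(xs * y[idx + k]), numeric(1)) / denom
  structure(list(lag = (0:L) * dt, g = g,
                 g_per_pixel = g * stimulus$pixel_step,
                 dt = dt, pixel_step = stimulus$pixel_step,
                 condition = trace$condition),
            class = "impulse_kernel")
}

# Profiled residual sum of squares for the double-exponential model: with the
# time constants fixed the amplitude enters linearly and is solved in closed
# form, leaving a 2-D search over (log tau_rise, log(tau_decay - tau_rise)).
.dexp_rss <- function(par, t, g) {
  tr <- exp(par[1])
  td <- tr + exp(par[2])
  m <- exp(-t / td) - exp(-t / tr)
  mm <- sum(m^2)
  if (!is.finite(mm) || mm < .Machine$double.eps) return(sum(g^2))
  a <- sum(m * g) / mm
  sum((g - a * m)^2)
}

#' Fit a double-exponential model to an impulse-response kernel
#'
#' Least-squares fit of `g(t) = amp * (exp(-t/tau_decay) - exp(-t/tau_rise))`
#' to an estimated kernel. Time constants are optimized on the log scale
#' (enforcing positivity and the ordering `tau_decay > tau_rise`) with the
#' amplitude profiled out linearly; the optimizer is restarted from a fixed
#' grid of starting values and the lowest-RSS solution is kept. The reported
#' peak amplitude and peak time come from the fitted curve (closed form), not
#' from the raw kernel samples.
#'
#' @param kernel An `impulse_kernel` (needs at least 10 lags), or a list with
#'   `lag` and `g`.
#' @param init Optional list with starting `tau_rise` and `tau_decay`,
#'   prepended to the default start grid.
#' @param n_starts Number of deterministic multi-starts (>= 5 by default).
#'
#' @return An object of class `double_exp_fit`: `amp`, `tau_rise`,
#'   `tau_decay`, `peak_amplitude`, `peak_time`, `rss`, `converged`. If no
#'   start converges the result is flagged (`converged = FALSE`) rather than
#'   raising an error.
#' @export
fit_double_exponential <- function(kernel, init = NULL, n_starts = 5) {
  t <- kernel$lag
  g <- kernel$g
  if (length(t) < 10) stop_invalid("kernel must have at least 10 lags")
  starts <- list(c(0.02, 0.15), c(0.01, 0.10), c(0.005, 0.05),
                 c(0.05, 0.30), c(0.10, 0.50), c(0.002, 0.02),
                 c(0.03, 0.60))
  if (!is.null(init))
    starts <- c(list(c(init$tau_rise, init$tau_decay)), starts)
  starts <- starts[seq_len(max(n_starts, length(init) > 0))]
  best <- NULL
  for (s in starts) {
    par0 <- c(log(s[1]), log(s[2] - s[1]))
    fit <- tryCatch(
      optim(par0, function(p) .dexp_rss(p, t, g), method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(amp = NA_real_, tau_rise = NA_real_,
                          tau_decay = NA_real_, peak_amplitude = NA_real_,
                          peak_time = NA_real_, rss = NA_real_,
                          converged = FALSE),
                     class = "double_exp_fit"))
  }
  tr <- exp(best$par[1])
  td <- tr + exp(best$par[2])
  m <- exp(-t / td) - exp(-t / tr)
  amp <- sum(m * g) / sum(m^2)
  pk <- double_exp_peak(amp, tr, td)
  structure(list(amp = amp, tau_rise = tr, tau_decay = td,
                 peak_amplitude = pk$peak_amplitude,
                 peak_time = pk$peak_time, rss = best$value,
                 converged = best$convergence == 0),
            class = "double_exp_fit")
}

#' Compare odor and water impulse-response peak amplitudes across flies
#'
#' Paired comparison of fitted kernel peak amplitudes between matched
#' water-control and odor trials of the same flies: a two-tailed paired t-test
#' on the per-fly peaks and the percent change of the group mean,
#' `100 * (mean_odor - mean_water) / mean_water`.
#'
#' @param fits_water List of `double_exp_fit` (or numeric peak amplitudes),
#'   one per fly, water condition.
#' @param fits_odor Matched list for the odor condition (same flies, same
#'   order).
#'
#' @return An object of class `odor_modulation_result`: `peaks` (tibble with
#'   fly, water, odor), `percent_change`, `t_statistic`, `p_value`, `df`,
#'   `n_flies`, `degenerate` (TRUE when the paired differences have zero
#'   variance, in which case p is reported as 1 for identical lists).
#' @export
compare_odor_modulation <- function(fits_water, fits_odor) {
  peak_of <- function(f) if (inherits(f, "double_exp_fit")) f$peak_amplitude
                         else as.numeric(f)
  w <- vapply(fits_water, peak_of, numeric(1))
  o <- vapply(fits_odor, peak_of, numeric(1))
  if (length(w) != length(o))
    stop_invalid("water and odor fit lists must be matched by fly")
  n <- length(w)
  if (n < 2) stop_invalid("need at least 2 flies for the paired test")
  mw <- mean(w)
  pct <- if (mw != 0) 100 * (mean(o) - mw) / mw else NA_real_
  d <- o - w
  degenerate <- isTRUE(all.equal(sd(d), 0)) || sd(d) == 0
  if (degenerate) {
    tt <- list(statistic = if (all(d == 0)) 0 else NaN,
               p.value = if (all(d == 0)) 1 else NaN,
               parameter = n - 1)
  } else {
    ht <- t.test(o, w, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value,
               parameter = unname(ht$parameter))
  }
  structure(list(peaks = tibble::tibble(fly = seq_len(n), water = w, odor = o),
                 percent_change = pct,
                 t_statistic = tt$statistic, p_value = tt$p.value,
                 df = tt$parameter, n_flies = n, degenerate = degenerate),
            class = "odor_modulation_result")
}

#' Run the full rigid-tether system-identification pipeline for one fly
#'
#' Convenience wrapper: simulate (or accept) paired water/odor trials, estimate
#' both kernels, and fit the double exponential to each.
#'
#' @param plant A `plant_params`.
#' @param duration,dt,pixel_step Stimulus parameters (defaults: 60 s, 0.01 s,
#'   3.75 degrees).
#' @param max_lag Kernel lag horizon in seconds.
#' @param seed Integer seed; stimulus and the two noise draws are derived
#'   from it.
#' @return List with `water` and `odor` `double_exp_fit`s and the two
#'   estimated kernels.
#' @export
sysid_single_fly <- function(plant = plant_params(), duration = 60,
                             dt = 0.01, pixel_step = 3.75, max_lag = 1,
                             seed = 1) {
  seed <- as.integer(seed)
  stim <- gen_white_noise_stimulus(duration, dt, pixel_step, seed = seed)
  yw <- simulate_steering_plant(stim, plant, odor_on = FALSE,
                                seed = derive_seed(seed, 1))
  yo <- simulate_steering_plant(stim, plant, odor_on = TRUE,
                                seed = derive_seed(seed, 2))
  kw <- estimate_impulse_response(stim, yw, max_lag)
  ko <- estimate_impulse_response(stim, yo, max_lag)
  list(water = fit_double_exponential(kw), odor = fit_double_exponential(ko),
       kernel_water = kw, kernel_odor = ko)
}
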