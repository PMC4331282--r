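#' Build a tuning curve from per-fly peak responses
#'
#' Mean +/- SEM of peak dF/F per stimulus value across flies.
#'
#' @param responses Tibble/data frame with columns `fly_id`,
#'   `stimulus_value`, `peak_dff` (as produced by
#'   [simulate_tuning_responses()]).
#' @return An object of class `tuning_curve`: tibble with `stimulus_value`,
#'   `mean_response`, `sem`, `n_flies`.
#' @export
tuning_curve <- function(responses) {
  vals <- unique(responses$stimulus_value)
  out <- do.call(rbind, lapply(vals, function(v) {
    x <- responses$peak_dff[responses$stimulus_value == v]
    tibble::tibble(stimulus_value = v, mean_response = mean(x),
                   sem = .sem(x), n_flies = length(x))
  }))
  structure(out, class = c("tuning_curve", class(out)))
}

#' Fit a Gaussian azimuthal receptive field
#'
#' Least-squares fit of
#' `response(az) = baseline + amplitude * exp(-4 ln2 (az - center)^2 / fwhm^2)`
#' to a tuning curve over azimuth; `fwhm` is reported as the receptive-field
#' width. A flat curve (or a failed fit) returns a flagged result instead of
#' an error.
#'
#' @param curve A `tuning_curve` over azimuth (needs >= 5 samples), or a data
#'   frame with `stimulus_value` and `mean_response`.
#' @return An object of class `rf_fit`: `center`, `fwhm`, `amplitude`,
#'   `baseline`, `rss`, `converged`.
#' @export
fit_azimuthal_rf <- function(curve) {
  az <- as.numeric(curve$stimulus_value)
  y <- curve$mean_response
  if (length(az) < 5) stop_invalid("need at least 5 azimuth samples")
  failed <- function() structure(list(center = NA_real_, fwhm = NA_real_,
                                      amplitude = NA_real_,
                                      baseline = NA_real_, rss = NA_real_,
                                      converged = FALSE), class = "rf_fit")
  if (diff(range(y)) < 1e-10) return(failed())
  dat <- data.frame(az = az, y = y)
  span <- diff(range(az))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * exp(-4 * log(2) * (az - c0)^2 / w^2), data = dat,
      start = list(b = min(y), a = diff(range(y)),
                   c0 = az[which.max(y)], w = span / 4),
      lower = c(-Inf, -Inf, min(az) - span, 1e-3),
      upper = c(Inf, Inf, max(az) + span, 10 * span),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  p <- coef(fit)
  structure(list(center = unname(p["c0"]), fwhm = abs(unname(p["w"])),
                 amplitude = unname(p["a"]), baseline = unname(p["b"]),
                 rss = sum(stats::resid(fit)^2), converged = TRUE),
            class = "rf_fit")
}

#' Bar-width response curve and monotonicity statistic
#'
#' Mean +/- SEM response per bar width, with the Spearman rank correlation of
#' mean response against width as the monotonicity statistic (1 for strictly
#' increasing, 0 when the curve is flat).
#'
#' @param responses Data frame with `fly_id`, `stimulus_value` (width,
#'   degrees), `peak_dff`.
#' @return List with `curve` (a `tuning_curve`) and `spearman_rho`.
#' @export
bar_width_curve <- function(responses) {
  cv <- tuning_curve(responses)
  m <- cv$mean_response
  rho <- if (sd(m) == 0) 0 else
    suppressWarnings(cor(as.numeric(cv$stimulus_value), m,
                         method = "spearman"))
  list(curve = cv, spearman_rho = rho)
}

#' Direction tuning normalized to the maximum response
#'
#' Per-direction mean responses divided by the largest mean response (so the
#' maximum is exactly 1), with the preferred direction the argmax; exact ties
#' report all maximizers. The output is scale-free: rescaling the input by
#' any positive constant leaves it unchanged.
#'
#' @param responses Data frame with `fly_id`, `stimulus_value` (direction
#'   label or degrees), `peak_dff`.
#' @return List with `curve` (tibble: `direction`, `mean_response`,
#'   `normalized`, `sem`, `n_flies`) and `preferred` (character/numeric
#'   vector of maximizing directions).
#' @export
direction_tuning <- function(responses) {
  cv <- tuning_curve(responses)
  mx <- max(cv$mean_response)
  if (mx <= 0) stop_invalid("maximum mean response must be positive")
  normalized <- cv$mean_response / mx
  pref <- cv$stimulus_value[normalized >= 1 - 1e-12]
  list(curve = tibble::tibble(direction = cv$stimulus_value,
                              mean_response = cv$mean_response,
                              normalized = normalized, sem = cv$sem,
                              n_flies = cv$n_flies),
       preferred = pref)
}

#' Temporal-frequency optimum from a tuning curve
#'
#' Least-squares fit of the log-Gaussian
#' `response(f) = b + a * exp(-(log2 f - log2 f_opt)^2 / (2 w^2))` to a
#' tuning curve over temporal frequency (Hz). Falls back to the sampled
#' argmax when the fit fails, and flags the result as a boundary case when
#' the optimum lies at or beyond the sampled range.
#'
#' @param curve A `tuning_curve` over frequency (>= 4 samples; log-spaced
#'   sampling recommended).
#' @return List with `f_opt` (Hz), `width_octaves`, `amplitude`, `baseline`,
#'   `method` ("fit" or "argmax"), `boundary` flag.
#' @export
temporal_frequency_optimum <- function(curve) {
  f <- as.numeric(curve$stimulus_value)
  y <- curve$mean_response
  if (length(f) < 4) stop_invalid("need at least 4 frequencies")
  o <- order(f); f <- f[o]; y <- y[o]
  argmax_result <- function() {
    fo <- f[which.max(y)]
    list(f_opt = fo, width_octaves = NA_real_, amplitude = NA_real_,
         baseline = NA_real_, method = "argmax",
         boundary = which.max(y) %in% c(1L, length(f)))
  }
  dat <- data.frame(lf = log2(f), y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * exp(-(lf - lfo)^2 / (2 * w^2)), data = dat,
      start = list(b = min(y), a = diff(range(y)),
                   lfo = log2(f[which.max(y)]), w = 1),
      lower = c(-Inf, 0, log2(min(f)) - 5, 0.05),
      upper = c(Inf, Inf, log2(max(f)) + 5, 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(argmax_result())
  p <- coef(fit)
  fo <- 2^unname(p["lfo"])
  list(f_opt = fo, width_octaves = unname(p["w"]),
       amplitude = unname(p["a"]), baseline = unname(p["b"]),
       method = "fit", boundary = fo <= min(f) || fo >= max(f))
}

#' Temporal frequency of a drifting grating
#'
#' `tf = speed / wavelength`: a square-wave grating of 27-degree wavelength
#' moving at the arena speed of 22 degrees/s has a temporal frequency of
#' about 0.815 Hz.
#'
#' @param speed Grating speed, degrees/s.
#' @param wavelength Spatial wavelength, degrees.
#' @return Temporal frequency in Hz.
#' @export
temporal_frequency <- function(speed, wavelength) {
  if (any(wavelength <= 0)) stop_invalid("wavelength must be > 0")
  speed / wavelength
}
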