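#' The eight arena motion directions
#'
#' Compass-like direction convention for the LED arena, in degrees, with
#' back-to-front motion over the ipsilateral eye as the 0-degree reference.
#'
#' @return Named numeric vector of 8 directions (degrees).
#' @export
arena_directions <- function() {
  setNames(seq(0, 315, by = 45),
           c("back_to_front", "btf_up", "up", "ftb_up",
             "front_to_back", "ftb_down", "down", "btf_down"))
}

.direction_deg <- function(d) {
  if (is.character(d)) {
    dirs <- arena_directions()
    if (!d %in% names(dirs)) stop_invalid("unknown direction label: ", d)
    unname(dirs[d])
  } else as.numeric(d)
}

#' Tuned visual cell model for calcium-trace synthesis
#'
#' Parameterizes the visual and olfactory response properties of an imaged
#' cell type. The visual drive to a stimulus is the product of a Gaussian
#' azimuthal receptive-field weight, a von Mises direction weight, and a
#' log-Gaussian temporal-frequency weight, scaled by `resp_amp` (the dF/F at
#' the preferred stimulus). Odor epochs multiply the visual drive by
#' `odor_gain`; `odor_direct_drive` adds a direct (vision-independent) odor
#' response, as for octopaminergic Tdc2 terminals.
#'
#' @param cell_type Label ("Hx", "T4T5", "HSE", "Tdc2", ...).
#' @param rf_center Receptive-field center, degrees azimuth (default 25, just
#'   ipsilateral to the visual midline).
#' @param rf_fwhm Receptive-field full width at half maximum, degrees
#'   (default 50).
#' @param preferred_direction One of the 8 arena directions (label or
#'   degrees); default back-to-front.
#' @param direction_conc Von Mises concentration (tuning sharpness).
#' @param tf_optimum Temporal-frequency optimum, Hz (default 1).
#' @param tf_logwidth Log-Gaussian tuning width, octaves (default 1.5).
#' @param odor_gain Multiplicative gain on visual drive during odor (Hx
#'   default 1.2; fixed at 1 for T4T5 and HSE).
#' @param odor_direct_drive Direct odor-evoked dF/F amplitude (Tdc2; default
#'   0).
#' @param indicator_tau Calcium-indicator decay time constant, seconds
#'   (default 0.6).
#' @param resp_amp dF/F amplitude at the preferred visual stimulus (default
#'   1).
#' @return An object of class `cell_model`.
#' @export
cell_model <- function(cell_type = "Hx", rf_center = 25, rf_fwhm = 50,
                       preferred_direction = "back_to_front",
                       direction_conc = 2, tf_optimum = 1, tf_logwidth = 1.5,
                       odor_gain = 1.2, odor_direct_drive = 0,
                       indicator_tau = 0.6, resp_amp = 1) {
  if (rf_fwhm <= 0) stop_invalid("rf_fwhm must be > 0")
  if (tf_optimum <= 0) stop_invalid("tf_optimum must be > 0")
  if (cell_type %in% c("T4T5", "HSE") && odor_gain != 1)
    stop_invalid("odor_gain must be exactly 1 for ", cell_type)
  structure(list(cell_type = cell_type, rf_center = rf_center,
                 rf_fwhm = rf_fwhm,
                 preferred_direction = .direction_deg(preferred_direction),
                 direction_conc = direction_conc, tf_optimum = tf_optimum,
                 tf_logwidth = tf_logwidth, odor_gain = odor_gain,
                 odor_direct_drive = odor_direct_drive,
                 indicator_tau = indicator_tau, resp_amp = resp_amp),
            class = "cell_model")
}

#' Stock cell models for the imaged cell types
#'
#' `Hx`: odor-modulated LPTC (odor_gain 1.2). `T4T5`, `HSE`: motion-tuned but
#' not odor-modulated (odor_gain fixed at 1). `Tdc2`: no visual drive, direct
#' odor response.
#'
#' @param cell_type One of "Hx", "T4T5", "HSE", "Tdc2".
#' @return A `cell_model`.
#' @export
stock_cell_model <- function(cell_type) {
  switch(cell_type,
    Hx   = cell_model("Hx"),
    T4T5 = cell_model("T4T5", odor_gain = 1),
    HSE  = cell_model("HSE", odor_gain = 1),
    Tdc2 = cell_model("Tdc2", odor_gain = 1, resp_amp = 0,
                      odor_direct_drive = 0.8),
    stop_invalid("unknown cell type: ", cell_type))
}

#' Tuned drive amplitude of a cell model to a visual condition
#'
#' Steady-state dF/F drive for a stimulus record: a list with `kind`
#' ("bar", "grating", "bar_width", or "none") and the applicable fields
#' `azimuth` (deg), `direction` (label or deg), `tf` (Hz), `width` (deg).
#' Bars engage the receptive-field (or bar-width) and direction weights;
#' full-field gratings engage direction and temporal-frequency weights. The
#' bar-width weight integrates the Gaussian receptive-field profile over the
#' bar extent, giving a saturating width dependence.
#'
#' @param cell A `cell_model`.
#' @param stimulus Stimulus record (list), see Details.
#' @return Scalar drive in dF/F units.
#' @export
cell_response <- function(cell, stimulus) {
  stopifnot(inherits(cell, "cell_model"))
  kind <- stimulus$kind %||% "none"
  if (kind == "none") return(0)
  dir_w <- if (is.null(stimulus$direction)) 1 else {
    d <- .direction_deg(stimulus$direction)
    exp(cell$direction_conc *
          (cos((d - cell$preferred_direction) * pi / 180) - 1))
  }
  tf_w <- if (is.null(stimulus$tf)) 1 else
    exp(-(log2(stimulus$tf) - log2(cell$tf_optimum))^2 /
          (2 * cell$tf_logwidth^2))
  spatial_w <- switch(kind,
    bar = exp(-4 * log(2) * (stimulus$azimuth - cell$rf_center)^2 /
                cell$rf_fwhm^2),
    bar_width = {
      s <- cell$rf_fwhm / (2 * sqrt(2 * log(2)))
      w <- stimulus$width
      pnorm(w / 2, 0, s) - pnorm(-w / 2, 0, s)
    },
    grating = 1,
    stop_invalid("unknown stimulus kind: ", kind))
  cell$resp_amp * spatial_w * dir_w * tf_w
}

#' Epoch schedule for the odor-pairing imaging protocol
#'
#' Five repeated 10-s epochs of wide-field motion interspersed with 10-s rest
#' periods; the odor pulse (10 s) accompanies the motion epoch
#' `odor_epoch_index` (default the second).
#'
#' @param n_epochs Number of motion epochs (default 5).
#' @param motion_duration Motion epoch length, s (default 10).
#' @param rest_duration Rest between epochs, s (default 10); also the initial
#'   rest before the first epoch.
#' @param odor_epoch_index 1-based index of the odor-paired epoch (default 2).
#' @param odor_duration Odor pulse length, s (default 10).
#' @return An object of class `epoch_design`.
#' @export
epoch_design <- function(n_epochs = 5, motion_duration = 10,
                         rest_duration = 10, odor_epoch_index = 2,
                         odor_duration = 10) {
  if (n_epochs < 1 || motion_duration <= 0 || rest_duration <= 0 ||
      odor_duration <= 0)
    stop_invalid("epoch design durations must be positive")
  if (odor_epoch_index < 1 || odor_epoch_index > n_epochs)
    stop_invalid("odor_epoch_index must lie in [1, n_epochs]")
  structure(list(n_epochs = n_epochs, motion_duration = motion_duration,
                 rest_duration = rest_duration,
                 odor_epoch_index = odor_epoch_index,
                 odor_duration = odor_duration),
            class = "epoch_design")
}

#' Motion-epoch and odor windows of an epoch design
#'
#' @param design An `epoch_design`.
#' @return List with `epochs` (n x 2 matrix of \[start, end) motion windows,
#'   seconds), `odor` (length-2 odor window), `total` (schedule length, s).
#' @export
epoch_windows <- function(design) {
  stopifnot(inherits(design, "epoch_design"))
  period <- design$motion_duration + design$rest_duration
  starts <- design$rest_duration + (seq_len(design$n_epochs) - 1) * period
  epochs <- cbind(start = starts, end = starts + design$motion_duration)
  odor_start <- starts[design$odor_epoch_index]
  list(epochs = epochs,
       odor = c(odor_start, odor_start + design$odor_duration),
       total = design$rest_duration + design$n_epochs * period)
}

#' Simulate a single-ROI calcium fluorescence trace
#'
#' Builds the tuned visual drive over the epoch schedule (zero during rest,
#' `cell_response()` during motion, multiplied by the cell's `odor_gain`
#' within the odor window, plus `odor_direct_drive` during the odor pulse),
#' convolves it with a single-exponential indicator kernel of unit DC gain,
#' and forms `F(t) = F0 * (1 + drive_filtered) + noise`. Fluorescence is
#' floored at a small positive value so traces are strictly positive.
#'
#' @param cell A `cell_model`.
#' @param design An `epoch_design`.
#' @param stimulus_params Visual condition record for the motion epochs
#'   (default full-field back-to-front grating at the arena speed).
#' @param noise_sd Gaussian noise SD in dF/F units (default 0.03).
#' @param f0 Baseline fluorescence, a.u. (default 100).
#' @param fs Frame rate, Hz (default 10, within the 8-11 Hz acquisition
#'   range).
#' @param seed Integer seed.
#' @param roi_id,fly_id Identifiers.
#' @return An object of class `roi_trace`: `time`, `F`, `roi_id`, `fly_id`,
#'   `cell_type`, `dt`.
#' @export
simulate_roi_trace <- function(cell, design = epoch_design(),
                               stimulus_params = list(kind = "grating",
                                 direction = "back_to_front",
                                 tf = 22 / 27),
                               noise_sd = 0.03, f0 = 100, fs = 10,
                               seed = NULL, roi_id = "roi1",
                               fly_id = "fly1") {
  stopifnot(inherits(cell, "cell_model"), inherits(design, "epoch_design"))
  win <- epoch_windows(design)
  dt <- 1 / fs
  time <- seq(0, win$total - dt, by = dt)
  drive <- numeric(length(time))
  base <- cell_response(cell, stimulus_params)
  for (k in seq_len(design$n_epochs)) {
    sel <- time >= win$epochs[k, 1] & time < win$epochs[k, 2]
    drive[sel] <- base
  }
  odor_sel <- time >= win$odor[1] & time < win$odor[2]
  drive[odor_sel] <- drive[odor_sel] * cell$odor_gain
  drive[odor_sel] <- drive[odor_sel] + cell$odor_direct_drive
  a <- exp(-dt / cell$indicator_tau)
  cal <- as.numeric(stats::filter((1 - a) * drive, a, method = "recursive"))
  f <- f0 * (1 + cal)
  if (noise_sd > 0)
    f <- f + with_seed(seed, rnorm(length(f), 0, noise_sd * f0))
  f <- pmax(f, 1e-6 * f0)
  structure(list(time = time, F = f, roi_id = roi_id, fly_id = fly_id,
                 cell_type = cell$cell_type, dt = dt),
            class = "roi_trace")
}

#' Simulate a cohort of flies for an epoch-structured imaging experiment
#'
#' @param cell A `cell_model`.
#' @param n_flies Number of animals.
#' @param design An `epoch_design`.
#' @param stimulus_params,noise_sd,fs See [simulate_roi_trace()].
#' @param seed Base seed; fly `i` uses `seed + i`.
#' @return List of `roi_trace` objects.
#' @export
simulate_imaging_cohort <- function(cell, n_flies = 13,
                                    design = epoch_design(),
                                    stimulus_params = list(kind = "grating",
                                      direction = "back_to_front",
                                      tf = 22 / 27),
                                    noise_sd = 0.03, fs = 10, seed = 1) {
  seed <- as.integer(seed)
  lapply(seq_len(n_flies), function(i) {
    simulate_roi_trace(cell, design, stimulus_params, noise_sd = noise_sd,
                       fs = fs, seed = seed + i,
                       roi_id = "roi1", fly_id = sprintf("fly%02d", i))
  })
}

#' Simulate per-fly peak dF/F tuning responses
#'
#' Steady-state peak responses (tuned drive plus Gaussian noise) for a sweep
#' over one stimulus dimension, as used for the receptive-field, bar-width,
#' direction, and temporal-frequency analyses.
#'
#' @param cell A `cell_model`.
#' @param kind One of "rf" (a narrow bar stepped across azimuth), "width"
#'   (bars of increasing width at the RF center), "direction" (full-field
#'   grating in the 8 arena directions), "tf" (grating at varying temporal
#'   frequency).
#' @param values Stimulus values swept (azimuths, widths, direction labels or
#'   degrees, frequencies). Defaults per kind.
#' @param n_flies Number of animals (default 7).
#' @param noise_sd Per-measurement noise SD, dF/F units (default 0.05).
#' @param seed Integer seed.
#' @return Tibble: `fly_id`, `stimulus_kind`, `stimulus_value`, `peak_dff`.
#' @export
simulate_tuning_responses <- function(cell, kind, values = NULL, n_flies = 7,
                                      noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(cell, "cell_model"))
  if (is.null(values)) {
    values <- switch(kind,
      rf = seq(-108, 108, by = 13.5),
      width = c(4, 8, 15, 30, 60, 120),
      direction = names(arena_directions()),
      tf = 2^seq(-2, 3, length.out = 6),
      stop_invalid("unknown tuning kind: ", kind))
  }
  stim_of <- function(v) switch(kind,
    rf = list(kind = "bar", azimuth = as.numeric(v),
              direction = cell$preferred_direction),
    width = list(kind = "bar_width", width = as.numeric(v),
                 direction = cell$preferred_direction),
    direction = list(kind = "grating", direction = v,
                     tf = cell$tf_optimum),
    tf = list(kind = "grating", direction = cell$preferred_direction,
              tf = as.numeric(v)))
  mu <- vapply(values, function(v) cell_response(cell, stim_of(v)),
               numeric(1))
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_flies), function(i) {
      tibble::tibble(fly_id = sprintf("fly%02d", i), stimulus_kind = kind,
                     stimulus_value = if (kind == "direction")
                       as.character(values) else as.numeric(values),
                     peak_dff = mu + rnorm(length(mu), 0, noise_sd))
    }))
  })
}
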