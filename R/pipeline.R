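#' Build the run configuration for a named experiment scenario
#'
#' Scenarios bundle the generator and analysis parameters of the study's
#' experiments:
#' \describe{
#'   \item{rigid_odor}{15 flies, paired odor/water rigid-tether trials,
#'     white-noise system identification of the optomotor kernel.}
#'   \item{plume_t4t5}{magnetic-tether plume tracking: T4T5-blocked
#'     (n = 25) against its two parental controls (n = 20, 19).}
#'   \item{hx_pairing}{13 flies, Hx calcium imaging under the five-epoch
#'     odor-pairing protocol.}
#'   \item{water_control}{6 flies, same protocol with water vapor instead of
#'     odor (visual odor gain 1).}
#'   \item{t4t5_imaging, hse_imaging}{6 flies each, odor-pairing protocol on
#'     cell types without odor modulation.}
#'   \item{tdc2_odor}{6 flies, octopaminergic terminals, stationary pattern,
#'     direct odor response; odor-on vs odor-off paired comparison.}
#'   \item{vmat_rescue}{plume tracking of VMAT-rescued (n = 32) vs
#'     trafficking-mutant d3VMAT (n = 21) flies plus a water control
#'     (n = 32); total time in plume.}
#' }
#'
#' @param scenario Scenario name (see Details).
#' @param seed Integer seed for every random draw of the run.
#' @return A `run_config` list.
#' @export
scenario_config <- function(scenario, seed = 1) {
  seed <- as.integer(seed)
  base <- list(scenario = scenario, seed = seed)
  cfg <- switch(scenario,
    rigid_odor = c(base, list(
      kind = "rigid", n_flies = 15,
      plant = list(amp = 1, tau_rise = 0.02, tau_decay = 0.15,
                   odor_gain = 1.4, noise_sd = 30),
      stimulus = list(duration = 60, dt = 0.01, pixel_step = 3.75),
      analysis = list(max_lag = 1))),
    plume_t4t5 = c(base, list(
      kind = "plume",
      groups = list(GAL4_control = list(profile = "control", n = 20),
                    UAS_control = list(profile = "control", n = 19),
                    T4T5_blocked = list(profile = "T4T5_blocked", n = 25)),
      trial = list(plume_azimuth = 180, duration = 40, dt = 0.02),
      analysis = list(threshold = 10, min_dwell = 0.5, phase_window = 10))),
    vmat_rescue = c(base, list(
      kind = "plume",
      groups = list(VMAT_rescue = list(profile = "VMAT_rescue", n = 32),
                    d3VMAT = list(profile = "d3VMAT", n = 21),
                    rescue_water = list(profile = "water", n = 32)),
      trial = list(plume_azimuth = 180, duration = 40, dt = 0.02),
      analysis = list(threshold = 10, min_dwell = 0.5, phase_window = 10))),
    hx_pairing = c(base, list(
      kind = "imaging", n_flies = 13, cell = "Hx",
      design = list(n_epochs = 5, motion_duration = 10, rest_duration = 10,
                    odor_epoch_index = 2, odor_duration = 10),
      imaging = list(noise_sd = 0.03, fs = 10),
      analysis = list(lag_pad = 2))),
    water_control = c(base, list(
      kind = "imaging", n_flies = 6, cell = "Hx_water",
      design = list(n_epochs = 5, motion_duration = 10, rest_duration = 10,
                    odor_epoch_index = 2, odor_duration = 10),
      imaging = list(noise_sd = 0.03, fs = 10),
      analysis = list(lag_pad = 2))),
    t4t5_imaging = c(base, list(
      kind = "imaging", n_flies = 6, cell = "T4T5",
      design = list(n_epochs = 5, motion_duration = 10, rest_duration = 10,
                    odor_epoch_index = 2, odor_duration = 10),
      imaging = list(noise_sd = 0.03, fs = 10),
      analysis = list(lag_pad = 2))),
    hse_imaging = c(base, list(
      kind = "imaging", n_flies = 7, cell = "HSE",
      design = list(n_epochs = 5, motion_duration = 10, rest_duration = 10,
                    odor_epoch_index = 2, odor_duration = 10),
      imaging = list(noise_sd = 0.03, fs = 10),
      analysis = list(lag_pad = 2))),
    tdc2_odor = c(base, list(
      kind = "imaging", n_flies = 6, cell = "Tdc2",
      design = list(n_epochs = 5, motion_duration = 10, rest_duration = 10,
                    odor_epoch_index = 2, odor_duration = 10),
      imaging = list(noise_sd = 0.03, fs = 10),
      analysis = list(lag_pad = 2, on_off_stat = "max"))),
    stop_invalid("unknown scenario: ", scenario))
  structure(cfg, class = "run_config")
}

.cell_from_config <- function(config) {
  if (config$cell == "Hx_water") cell_model("Hx", odor_gain = 1)
  else stock_cell_model(config$cell)
}

#' Validate a run configuration
#'
#' Checks every invariant declared by the domain types used by the
#' configuration (plant parameters, epoch design, agent profiles, analysis
#' thresholds) and returns the violations found.
#'
#' @param config A `run_config` (or plain list with the same fields).
#' @return Character vector of violations; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  note <- function(type, msg) sprintf("%s: %s", type, msg)
  if (is.null(config$kind) ||
      !config$kind %in% c("rigid", "plume", "imaging"))
    v <- c(v, note("RunConfig", "kind must be rigid, plume, or imaging"))
  if (is.null(config$seed) || !is.finite(config$seed))
    v <- c(v, note("RunConfig", "seed must be a finite integer"))
  if (!is.null(config$plant)) {
    msg <- tryCatch({do.call(plant_params, config$plant); NULL},
                    error = function(e) conditionMessage(e))
    if (!is.null(msg)) v <- c(v, note("PlantParams", msg))
  }
  if (!is.null(config$design)) {
    msg <- tryCatch({do.call(epoch_design, config$design); NULL},
                    error = function(e) conditionMessage(e))
    if (!is.null(msg)) v <- c(v, note("EpochDesign", msg))
  }
  if (!is.null(config$groups)) {
    for (g in names(config$groups)) {
      msg <- tryCatch({stock_profile(config$groups[[g]]$profile); NULL},
                      error = function(e) conditionMessage(e))
      if (!is.null(msg)) v <- c(v, note("AgentProfile", msg))
      n <- config$groups[[g]]$n
      if (is.null(n) || n < 1)
        v <- c(v, note("RunConfig", paste0("group ", g, " needs n >= 1")))
    }
  }
  a <- config$analysis
  if (!is.null(a$threshold) && a$threshold <= 0)
    v <- c(v, note("PlumeMetrics", "threshold must be > 0"))
  if (!is.null(a$max_lag) && a$max_lag <= 0)
    v <- c(v, note("ImpulseKernel", "max_lag must be > 0"))
  v
}

.run_rigid <- function(config) {
  plant <- do.call(plant_params, config$plant)
  st <- config$stimulus
  flies <- lapply(seq_len(config$n_flies), function(i) {
    sysid_single_fly(plant, duration = st$duration, dt = st$dt,
                     pixel_step = st$pixel_step,
                     max_lag = config$analysis$max_lag,
                     seed = derive_seed(config$seed, i))
  })
  fit_row <- function(f, i, cond) tibble::tibble(
    fly_id = sprintf("fly%02d", i), condition = cond, amp = f$amp,
    tau_rise = f$tau_rise, tau_decay = f$tau_decay,
    peak_amplitude = f$peak_amplitude, peak_time = f$peak_time, rss = f$rss)
  fits <- do.call(rbind, lapply(seq_along(flies), function(i)
    rbind(fit_row(flies[[i]]$water, i, "water"),
          fit_row(flies[[i]]$odor, i, "odor"))))
  mod <- compare_odor_modulation(lapply(flies, `[[`, "water"),
                                 lapply(flies, `[[`, "odor"))
  list(tables = list(kernel_fits = fits),
       stats = list(odor_modulation = list(
         percent_change = mod$percent_change,
         t_statistic = mod$t_statistic, p_value = mod$p_value,
         n_flies = mod$n_flies)),
       objects = list(modulation = mod, flies = flies))
}

.run_plume <- function(config) {
  tr <- config$trial
  traces <- list()
  gi <- 0L
  for (g in names(config$groups)) {
    gi <- gi + 1L
    spec <- config$groups[[g]]
    prof <- stock_profile(spec$profile)
    prof$label <- g
    for (i in seq_len(spec$n)) {
      traces[[length(traces) + 1L]] <- simulate_plume_flight(
        prof, plume_azimuth = tr$plume_azimuth, duration = tr$duration,
        dt = tr$dt, seed = derive_seed(config$seed, i, gi))
    }
  }
  a <- config$analysis
  cmp <- summarize_plume_tracking(traces, threshold = a$threshold,
                                  min_dwell = a$min_dwell,
                                  phase_window = a$phase_window)
  list(tables = list(per_fly_metrics = cmp$per_fly,
                     group_summary = cmp$group_summary,
                     pairwise_tests = cmp$pairwise),
       stats = list(detection_test = cmp$detection_test),
       objects = list(comparison = cmp, traces = traces))
}

.run_imaging <- function(config) {
  cell <- .cell_from_config(config)
  design <- do.call(epoch_design, config$design)
  stim <- if (cell$cell_type == "Tdc2") list(kind = "none")
          else list(kind = "grating", direction = "back_to_front",
                    tf = 22 / 27)
  traces <- simulate_imaging_cohort(cell, config$n_flies, design, stim,
                                    noise_sd = config$imaging$noise_sd,
                                    fs = config$imaging$fs,
                                    seed = derive_seed(config$seed,
                                                       sum(utf8ToInt(config$cell))))
  dffs <- lapply(traces, compute_dff, design = design)
  resp <- lapply(dffs, epoch_peaks, design = design,
                 lag_pad = config$analysis$lag_pad)
  peaks <- do.call(rbind, lapply(resp, function(r) r$peaks))
  peak_tbl <- tibble::as_tibble(as.data.frame(peaks))
  names(peak_tbl) <- paste0("epoch", seq_len(design$n_epochs))
  peak_tbl <- cbind(tibble::tibble(
    fly_id = vapply(resp, function(r) r$fly_id, character(1))), peak_tbl)
  mod <- odor_modulation_test(resp)
  stats <- list(epoch_tests = mod$tests)
  if (cell$cell_type == "Tdc2") {
    win <- epoch_windows(design)
    on_w <- win$odor
    off_w <- c(win$odor[1] - design$odor_duration, win$odor[1])
    oo <- odor_on_off_test(dffs, on_w, off_w,
                           stat = config$analysis$on_off_stat %||% "max")
    stats$odor_on_off <- list(t_statistic = oo$t_statistic,
                              p_value = oo$p_value, n_flies = oo$n_flies)
  }
  list(tables = list(epoch_peaks = tibble::as_tibble(peak_tbl),
                     epoch_tests = mod$tests),
       stats = stats,
       objects = list(modulation = mod, traces = traces, dffs = dffs,
                      responses = resp))
}

#' Run a configured experiment end to end
#'
#' Dispatches a `run_config` to the matching generator and analysis modules
#' and returns (optionally writes) a results bundle. Re-running with the same
#' configuration and seed reproduces every numeric output exactly.
#'
#' @param config A `run_config` from [scenario_config()] (or equivalent
#'   list).
#' @param out_dir Optional output directory; when given, all tables are
#'   written as CSV and the stats and provenance as JSON via
#'   [write_bundle()].
#' @return An object of class `results_bundle`: `tables` (tibbles), `stats`,
#'   `objects` (in-memory analysis objects), `provenance` (seed, config
#'   hash, package version, timestamp).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  viol <- validate_config(config)
  if (length(viol))
    stop_invalid("invalid config:\n", paste("-", viol, collapse = "\n"))
  res <- switch(config$kind,
    rigid = .run_rigid(config),
    plume = .run_plume(config),
    imaging = .run_imaging(config))
  bundle <- structure(
    c(res, list(provenance = list(
        scenario = config$scenario %||% config$kind,
        seed = config$seed,
        config_hash = rlang::hash(unclass(config)),
        package_version = as.character(utils::packageVersion("odorgaze")),
        timestamp = format(Sys.time(), tz = "UTC")))),
    class = "results_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a results bundle to disk
#'
#' Tables go to `<name>.csv`, statistics to `stats.json`, provenance to
#' `provenance.json`. Numeric tables round-trip CSV -> memory -> CSV
#' losslessly at full double precision.
#'
#' @param bundle A `results_bundle`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$tables)) {
    tb <- bundle$tables[[nm]]
    if (is.null(tb)) next
    write.csv(tb, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(bundle$stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
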