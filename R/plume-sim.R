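#' Behavioral profile of a magnetically tethered fly
#'
#' Parameters of the heading dynamics used to emulate odor plume tracking in
#' the magnetic-tether arena. The fly senses the plume only while its heading
#' lies within `sensing_halfwidth` of the plume azimuth; inside that cone an
#' attraction term pulls the heading toward the plume, outside it the fly
#' performs a slow searching rotation. A slowly varying angular-velocity bias
#' models unstabilized drift; visual stabilization (`stabilization_gain`)
#' mean-reverts that bias, so a profile with `stabilization_gain = 0`
#' accumulates drift as a random walk and progressively loses the plume even
#' though its odor attraction is intact.
#'
#' @param label Genotype tag (e.g. "control", "T4T5_blocked", "VMAT_rescue",
#'   "d3VMAT").
#' @param attraction_gain Odor-driven pull toward the plume, 1/s (>= 0).
#' @param stabilization_gain Visual damping rate of the heading drift bias,
#'   1/s (>= 0).
#' @param heading_noise_sd Intensity of the white noise driving the drift
#'   bias, in degrees/s per sqrt(s) (>= 0).
#' @param search_rate Searching rotation speed outside the sensing cone,
#'   degrees/s.
#' @param sensing_halfwidth Half-width of the binary odor sensing cone,
#'   degrees (default 90).
#'
#' @return An object of class `agent_profile`.
#' @export
agent_profile <- function(label = "control", attraction_gain = 2.0,
                          stabilization_gain = 1.5, heading_noise_sd = 4.5,
                          search_rate = 25, sensing_halfwidth = 90) {
  if (attraction_gain < 0 || stabilization_gain < 0 || heading_noise_sd < 0)
    stop_invalid("gains and noise must be >= 0")
  structure(list(label = label, attraction_gain = attraction_gain,
                 stabilization_gain = stabilization_gain,
                 heading_noise_sd = heading_noise_sd,
                 search_rate = search_rate,
                 sensing_halfwidth = sensing_halfwidth),
            class = "agent_profile")
}

#' Stock behavioral profiles for the plume-tracking scenarios
#'
#' `control` is the calibrated wild-type profile; `T4T5_blocked` has intact
#' odor attraction but no visual stabilization (sustained tracking broken);
#' `VMAT_rescue` behaves as control; `d3VMAT` has strongly reduced odor
#' attraction; `water` has no odor attraction at all.
#'
#' @param label One of "control", "T4T5_blocked", "VMAT_rescue", "d3VMAT",
#'   "water".
#' @return An `agent_profile`.
#' @export
stock_profile <- function(label) {
  switch(label,
    control      = agent_profile("control"),
    T4T5_blocked = agent_profile("T4T5_blocked", stabilization_gain = 0),
    VMAT_rescue  = agent_profile("VMAT_rescue"),
    d3VMAT       = agent_profile("d3VMAT", attraction_gain = 0.15),
    water        = agent_profile("water", attraction_gain = 0),
    stop_invalid("unknown profile label: ", label))
}

#' Construct a heading trace
#'
#' @param time Time stamps in seconds (uniform grid).
#' @param heading Headings in degrees; wrapped into \[0, 360).
#' @param plume_azimuth Plume azimuth in degrees (arena convention: 180).
#' @param fly_id,group Identifiers carried through the metrics.
#' @return An object of class `heading_trace`.
#' @export
heading_trace <- function(time, heading, plume_azimuth = 180,
                          fly_id = "fly1", group = "control") {
  stopifnot(length(time) == length(heading))
  dts <- diff(time)
  if (length(dts) && (max(dts) - min(dts)) > 1e-8 * max(dts, 1))
    stop_invalid("heading trace requires a uniform time grid")
  structure(list(time = time, heading = heading %% 360,
                 plume_azimuth = plume_azimuth %% 360,
                 dt = if (length(dts)) dts[1] else NA_real_,
                 fly_id = fly_id, group = group),
            class = "heading_trace")
}

#' Simulate odor plume tracking on the magnetic tether
#'
#' Discrete-time circular heading dynamics. Per step of length `dt`:
#' \deqn{\Delta\theta = dt\,[k_a\,e(t)\,\mathbf{1}(|e|\le c) +
#'   s\,\omega_{search}\,\mathbf{1}(|e|>c) + b(t)]}
#' where `e(t)` is the signed shortest arc from heading to plume azimuth,
#' `c` the sensing half-width, and `b(t)` an Ornstein-Uhlenbeck
#' angular-velocity bias, `db = -k_s b dt + sigma sqrt(dt) dW`, damped at the
#' profile's `stabilization_gain` `k_s`. Headings are wrapped to \[0, 360).
#'
#' @param profile An `agent_profile`.
#' @param plume_azimuth Plume azimuth in degrees (default 180).
#' @param duration Trial length in seconds (default 40).
#' @param dt Integration step in seconds (default 0.02).
#' @param seed Integer seed.
#' @param theta0 Initial heading in degrees; `NULL` draws it uniformly.
#' @return A `heading_trace`.
#' @export
simulate_plume_flight <- function(profile, plume_azimuth = 180, duration = 40,
                                  dt = 0.02, seed = NULL, theta0 = NULL) {
  stopifnot(inherits(profile, "agent_profile"))
  if (duration <= 0 || dt <= 0) stop_invalid("duration and dt must be > 0")
  n <- as.integer(round(duration / dt))
  ka <- profile$attraction_gain
  ks <- profile$stabilization_gain
  sig <- profile$heading_noise_sd
  cone <- profile$sensing_halfwidth
  th <- numeric(n)
  with_seed(seed, {
    th[1] <- if (is.null(theta0)) runif(1, 0, 360) else theta0 %% 360
    sdir <- sample(c(-1, 1), 1)
    eps <- rnorm(n)
    b <- 0
    for (i in seq_len(n - 1L)) {
      err <- ((plume_azimuth - th[i] + 180) %% 360) - 180
      drift <- if (abs(err) <= cone) ka * err else profile$search_rate * sdir
      th[i + 1L] <- (th[i] + dt * (drift + b)) %% 360
      b <- b * (1 - ks * dt) + sig * sqrt(dt) * eps[i]
    }
  })
  heading_trace((seq_len(n) - 1) * dt, th, plume_azimuth,
                fly_id = paste0(profile$label, "_", seed %||% "x"),
                group = profile$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
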