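#' Shortest angular distance between two directions
#'
#' @param heading,target Angles in degrees (vectors recycle).
#' @return Absolute shortest-arc distance in degrees, in \[0, 180\].
#' @export
angular_distance <- function(heading, target) {
  abs(((heading - target + 180) %% 360) - 180)
}

.in_plume <- function(trace, threshold) {
  angular_distance(trace$heading, trace$plume_azimuth) <= threshold
}

#' Did the fly ever detect (orient to) the plume?
#'
#' Detection is a contiguous dwell of at least `min_dwell` seconds with the
#' heading within `threshold` degrees of the plume azimuth, anywhere in the
#' trial. The dwell requirement rejects single-sample fly-throughs.
#'
#' @param trace A `heading_trace`.
#' @param threshold Half-width of the plume cone in degrees (default 10).
#' @param min_dwell Minimum contiguous dwell in seconds (default 0.5).
#' @return Logical flag.
#' @export
detect_plume <- function(trace, threshold = 10, min_dwell = 0.5) {
  stopifnot(inherits(trace, "heading_trace"))
  inside <- .in_plume(trace, threshold)
  if (!any(inside)) return(FALSE)
  r <- rle(inside)
  any(r$lengths[r$values] * trace$dt >= min_dwell)
}

#' Time spent oriented within the plume over a window
#'
#' `dt` times the number of samples in the half-open window \[t0, t1) whose
#' heading lies within `threshold` degrees of the plume azimuth.
#'
#' @param trace A `heading_trace`.
#' @param window Numeric length-2, `c(t0, t1)` in seconds.
#' @param threshold Plume cone half-width in degrees (default 10).
#' @return Time in seconds.
#' @export
time_in_plume <- function(trace, window, threshold = 10) {
  stopifnot(inherits(trace, "heading_trace"), length(window) == 2)
  sel <- trace$time >= window[1] & trace$time < window[2]
  trace$dt * sum(.in_plume(trace, threshold)[sel])
}

#' Three-phase plume-tracking metrics for one trial
#'
#' Detection (ever dwelling within the plume cone), acquisition (time in plume
#' over the first `phase_window` seconds), continuous tracking (time in plume
#' over the final `phase_window` seconds), and total time in plume over the
#' whole trial. Acquisition and tracking are reported only for detecting
#' flies (`NA` otherwise), mirroring the exclusion of non-detectors.
#'
#' @param trace A `heading_trace`.
#' @param threshold Plume cone half-width, degrees (default 10).
#' @param min_dwell Detection dwell requirement, seconds (default 0.5).
#' @param phase_window Length of the acquisition/tracking windows, seconds
#'   (default 10).
#' @return A one-row tibble: `fly_id`, `group`, `detected`, `acquisition_s`,
#'   `tracking_s`, `total_s`.
#' @export
plume_metrics <- function(trace, threshold = 10, min_dwell = 0.5,
                          phase_window = 10) {
  total_dur <- trace$time[length(trace$time)] + trace$dt
  det <- detect_plume(trace, threshold, min_dwell)
  acq <- time_in_plume(trace, c(0, phase_window), threshold)
  trk <- time_in_plume(trace, c(total_dur - phase_window, total_dur),
                       threshold)
  tot <- time_in_plume(trace, c(0, total_dur), threshold)
  tibble::tibble(fly_id = trace$fly_id, group = trace$group, detected = det,
                 acquisition_s = if (det) acq else NA_real_,
                 tracking_s = if (det) trk else NA_real_,
                 total_s = tot)
}

.sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

#' Group-level plume-tracking summary and statistics
#'
#' Per group: detection proportion; among detected flies only, mean +/- SEM of
#' acquisition, tracking, and total time in plume. Across groups: a chi-square
#' test on the detection counts (no continuity correction by default, as for
#' the arena proportions) and pairwise unpaired two-tailed Welch t-tests on
#' the time metrics. Non-detecting flies are excluded before any time metric
#' is computed. With a single group only the per-group summary is returned.
#'
#' @param traces List of `heading_trace` objects (each carries its group
#'   label).
#' @param threshold,min_dwell,phase_window Passed to [plume_metrics()].
#' @param correct Continuity correction for the chi-square test (default
#'   FALSE).
#' @return An object of class `group_comparison`: `per_fly` (tibble),
#'   `group_summary` (tibble), `detection_test` (list or NULL),
#'   `pairwise` (tibble of pairwise Welch tests or NULL).
#' @export
summarize_plume_tracking <- function(traces, threshold = 10, min_dwell = 0.5,
                                     phase_window = 10, correct = FALSE) {
  if (length(traces) == 0) stop_invalid("no traces supplied")
  per_fly <- do.call(rbind, lapply(traces, plume_metrics,
                                   threshold = threshold,
                                   min_dwell = min_dwell,
                                   phase_window = phase_window))
  groups <- unique(per_fly$group)
  if (any(tabulate(factor(per_fly$group, groups)) == 0))
    stop_invalid("empty group")
  gs <- do.call(rbind, lapply(groups, function(g) {
    d <- per_fly[per_fly$group == g, ]
    det <- d$detected
    dd <- d[det, ]
    tibble::tibble(group = g, n = nrow(d), n_detected = sum(det),
                   detection_prop = mean(det),
                   acquisition_mean = mean(dd$acquisition_s),
                   acquisition_sem = .sem(dd$acquisition_s),
                   tracking_mean = mean(dd$tracking_s),
                   tracking_sem = .sem(dd$tracking_s),
                   total_mean = mean(dd$total_s),
                   total_sem = .sem(dd$total_s))
  }))
  detection_test <- NULL
  pairwise <- NULL
  if (length(groups) > 1) {
    tab <- cbind(gs$n_detected, gs$n - gs$n_detected)
    if (any(colSums(tab) == 0)) {
      # all flies detected (or none): identical proportions, nothing to test
      detection_test <- list(statistic = 0, df = length(groups) - 1,
                             p_value = 1)
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = correct))
      detection_test <- list(statistic = unname(ct$statistic),
                             df = unname(ct$parameter), p_value = ct$p.value)
    }
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    pairwise <- do.call(rbind, lapply(pairs, function(p) {
      do.call(rbind, lapply(c("acquisition_s", "tracking_s", "total_s"),
        function(metric) {
          a <- per_fly[per_fly$group == p[1] & per_fly$detected, ][[metric]]
          b <- per_fly[per_fly$group == p[2] & per_fly$detected, ][[metric]]
          ok <- length(a) > 1 && length(b) > 1 &&
            (sd(a) > 0 || sd(b) > 0)
          ht <- if (ok) t.test(a, b) else NULL
          tibble::tibble(group1 = p[1], group2 = p[2], metric = metric,
                         mean1 = mean(a), mean2 = mean(b),
                         t_statistic = if (ok) unname(ht$statistic)
                                       else NA_real_,
                         p_value = if (ok) ht$p.value
                                   else if (length(a) && length(b) &&
                                            isTRUE(all.equal(mean(a),
                                                             mean(b)))) 1
                                   else NA_real_)
        }))
    }))
  }
  structure(list(per_fly = per_fly, group_summary = gs,
                 detection_test = detection_test, pairwise = pairwise),
            class = "group_comparison")
}
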