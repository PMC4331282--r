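#' Construct an ROI fluorescence trace
#'
#' @param time Frame times in seconds (strictly increasing).
#' @param F Raw fluorescence, a.u. (> 0).
#' @param roi_id,fly_id,cell_type Identifiers.
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(time, F, roi_id = "roi1", fly_id = "fly1",
                      cell_type = NA_character_) {
  stopifnot(length(time) == length(F))
  if (any(diff(time) <= 0)) stop_invalid("time must be strictly increasing")
  if (any(F <= 0)) stop_invalid("fluorescence must be strictly positive")
  structure(list(time = time, F = F, roi_id = roi_id, fly_id = fly_id,
                 cell_type = cell_type,
                 dt = if (length(time) > 1) time[2] - time[1] else NA_real_),
            class = "roi_trace")
}

#' Compute dF/F from a raw fluorescence trace
#'
#' `dff(t) = (F(t) - F0) / F0` with `F0` the mean fluorescence over a
#' pre-stimulus baseline window. By default the window is the final 5 seconds
#' of the initial rest period of the supplied epoch design.
#'
#' @param trace An `roi_trace`.
#' @param design An `epoch_design` (used only to place the default baseline
#'   window).
#' @param baseline_window Optional explicit `c(t0, t1)` window, seconds
#'   (half-open), overriding the design default.
#' @return An object of class `dff_trace`: `time`, `dff`, `f0`, plus the
#'   trace identifiers.
#' @export
compute_dff <- function(trace, design = epoch_design(),
                        baseline_window = NULL) {
  stopifnot(inherits(trace, "roi_trace"))
  if (is.null(baseline_window)) {
    r <- design$rest_duration
    baseline_window <- c(max(0, r - 5), r)
  }
  sel <- trace$time >= baseline_window[1] & trace$time < baseline_window[2]
  if (sum(sel) < 3)
    stop_invalid("baseline window must contain at least 3 frames")
  f0 <- mean(trace$F[sel])
  if (f0 <= 0) stop_invalid("baseline F0 must be positive")
  structure(list(time = trace$time, dff = (trace$F - f0) / f0, f0 = f0,
                 roi_id = trace$roi_id, fly_id = trace$fly_id,
                 cell_type = trace$cell_type, dt = trace$dt),
            class = "dff_trace")
}

#' Per-epoch peak dF/F responses
#'
#' For each motion epoch, the maximum dF/F within
#' `[epoch_start, epoch_start + motion_duration + lag_pad)`; the lag pad
#' admits peaks delayed by the indicator decay.
#'
#' @param dff A `dff_trace`.
#' @param design An `epoch_design`.
#' @param lag_pad Post-epoch padding in seconds (default 2).
#' @return An object of class `epoch_response`: `peaks` (numeric,
#'   length `n_epochs`), `fly_id`.
#' @export
epoch_peaks <- function(dff, design = epoch_design(), lag_pad = 2) {
  stopifnot(inherits(dff, "dff_trace"), inherits(design, "epoch_design"))
  win <- epoch_windows(design)
  peaks <- vapply(seq_len(design$n_epochs), function(k) {
    sel <- dff$time >= win$epochs[k, 1] &
      dff$time < win$epochs[k, 2] + lag_pad
    if (!any(sel)) return(NA_real_)
    max(dff$dff[sel])
  }, numeric(1))
  structure(list(peaks = peaks, fly_id = dff$fly_id), class = "epoch_response")
}

#' Rank-sum tests of odor-epoch modulation across flies
#'
#' Wilcoxon rank-sum test comparing epoch-1 peak amplitudes (before the odor
#' pulse) against each subsequent epoch `k`, across flies, as in the
#' odor-pairing protocol. The paired signed-rank variant is reported
#' alongside, together with per-fly deltas relative to epoch 1.
#'
#' @param responses List of `epoch_response` objects (one per fly).
#' @return An object of class `odor_modulation_stats`: `peaks` (flies x
#'   epochs matrix), `tests` (tibble with epoch, W statistic, rank-sum p,
#'   signed-rank p, delta mean), `deltas` (flies x (n_epochs-1) matrix).
#' @export
odor_modulation_test <- function(responses) {
  if (length(responses) < 2) stop_invalid("need at least 2 flies")
  peaks <- do.call(rbind, lapply(responses, function(r) r$peaks))
  rownames(peaks) <- vapply(responses, function(r) r$fly_id, character(1))
  n_ep <- ncol(peaks)
  tests <- do.call(rbind, lapply(2:n_ep, function(k) {
    x <- peaks[, k]
    y <- peaks[, 1]
    if (all(x == y) && length(unique(c(x, y))) == 1) {
      w <- length(x)^2 / 2; p <- 1; ps <- 1
    } else {
      ht <- suppressWarnings(wilcox.test(x, y))
      w <- unname(ht$statistic); p <- ht$p.value
      ps <- suppressWarnings(wilcox.test(x, y, paired = TRUE))$p.value
    }
    tibble::tibble(epoch = k, w_statistic = w, p_value = p,
                   p_signed_rank = ps, delta_mean = mean(x - y),
                   enhanced = stats::median(x) > stats::median(y))
  }))
  deltas <- peaks[, -1, drop = FALSE] - peaks[, 1]
  structure(list(peaks = peaks, tests = tests, deltas = deltas),
            class = "odor_modulation_stats")
}

#' Paired odor-on versus odor-off comparison of dF/F
#'
#' Per fly, the summary statistic (max by default, or mean) of dF/F within an
#' odor-on window and a matched odor-off (pre-pulse) window, compared with a
#' two-tailed paired t-test across flies.
#'
#' @param dff_list List of `dff_trace` objects (one per fly).
#' @param on_window,off_window `c(t0, t1)` windows in seconds (half-open).
#' @param stat "max" (default) or "mean".
#' @return List with `per_fly` (tibble fly_id/off/on), `t_statistic`,
#'   `p_value`, `n_flies`, `degenerate` flag (zero-variance differences).
#' @export
odor_on_off_test <- function(dff_list, on_window, off_window, stat = "max") {
  fn <- switch(stat, max = max, mean = mean,
               stop_invalid("stat must be 'max' or 'mean'"))
  stat_in <- function(d, w) {
    sel <- d$time >= w[1] & d$time < w[2]
    if (!any(sel)) return(NA_real_)
    fn(d$dff[sel])
  }
  on <- vapply(dff_list, stat_in, numeric(1), w = on_window)
  off <- vapply(dff_list, stat_in, numeric(1), w = off_window)
  n <- length(on)
  if (n < 2) stop_invalid("need at least 2 flies")
  d <- on - off
  degenerate <- sd(d) == 0
  if (degenerate) {
    tt <- list(statistic = if (all(d == 0)) 0 else NaN,
               p.value = if (all(d == 0)) 1 else NaN)
  } else {
    ht <- t.test(on, off, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  list(per_fly = tibble::tibble(
         fly_id = vapply(dff_list, function(d) d$fly_id, character(1)),
         off = off, on = on),
       t_statistic = tt$statistic, p_value = tt$p.value, n_flies = n,
       degenerate = degenerate)
}

#' Quality-control screening of ROI traces
#'
#' Applies the three exclusion rules of the imaging protocol, each with a
#' reason code:
#' \describe{
#'   \item{movement}{frame-to-frame `|dF|/F` exceeds `jump_frac` in more than
#'     `jump_max_frac` of frames (movement artifact);}
#'   \item{bleaching}{a linear fit of F against time drifts down faster than
#'     `bleach_pct_per_min` percent of the mean per minute;}
#'   \item{responsiveness}{fewer than `min_responsive` motion epochs with a
#'     peak dF/F above `response_k` baseline noise SDs.}
#' }
#' The default thresholds are package conventions (the protocol states the
#' rules, not numeric cutoffs) and are echoed in the output.
#'
#' @param traces List of `roi_trace` objects.
#' @param design An `epoch_design`.
#' @param thresholds Named list overriding any of `jump_frac` (0.5),
#'   `jump_max_frac` (0.05), `bleach_pct_per_min` (20), `response_k` (2),
#'   `min_responsive` (2).
#' @param lag_pad Passed to [epoch_peaks()].
#' @return List with `included`, `excluded` (lists of traces), `report`
#'   (tibble: roi_id, fly_id, included, reasons), `thresholds`.
#' @export
qc_filter <- function(traces, design = epoch_design(), thresholds = list(),
                      lag_pad = 2) {
  th <- utils::modifyList(list(jump_frac = 0.5, jump_max_frac = 0.05,
                               bleach_pct_per_min = 20, response_k = 2,
                               min_responsive = 2), thresholds)
  assess <- function(tr) {
    reasons <- character(0)
    jumps <- abs(diff(tr$F)) / tr$F[-length(tr$F)]
    if (mean(jumps > th$jump_frac) > th$jump_max_frac)
      reasons <- c(reasons, "movement")
    sl <- coef(lm(tr$F ~ tr$time))[2]
    drift_pct_min <- 100 * sl * 60 / mean(tr$F)
    if (drift_pct_min < -th$bleach_pct_per_min)
      reasons <- c(reasons, "bleaching")
    resp <- tryCatch({
      d <- compute_dff(tr, design)
      r <- design$rest_duration
      base_sel <- d$time >= max(0, r - 5) & d$time < r
      noise_sd <- sd(d$dff[base_sel])
      # peaks taken on a ~0.5 s running mean so that the max over an epoch of
      # pure frame noise does not clear the threshold by chance alone
      k_sm <- max(1L, round(0.5 / d$dt))
      sm <- as.numeric(stats::filter(d$dff, rep(1 / k_sm, k_sm), sides = 2))
      dsm <- d
      dsm$dff <- ifelse(is.na(sm), 0, sm)
      pk <- epoch_peaks(dsm, design, lag_pad)$peaks
      sum(pk > th$response_k * noise_sd, na.rm = TRUE)
    }, error = function(e) 0)
    if (resp < th$min_responsive) reasons <- c(reasons, "responsiveness")
    reasons
  }
  reasons <- lapply(traces, assess)
  ok <- vapply(reasons, length, integer(1)) == 0
  report <- tibble::tibble(
    roi_id = vapply(traces, function(t) t$roi_id, character(1)),
    fly_id = vapply(traces, function(t) t$fly_id, character(1)),
    included = ok,
    reasons = vapply(reasons, function(r)
      if (length(r)) paste(r, collapse = ";") else "", character(1)))
  list(included = traces[ok], excluded = traces[!ok], report = report,
       thresholds = th)
}
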