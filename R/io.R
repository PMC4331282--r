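#' Write a synthetic experiment as tidy CSV plus a JSON sidecar
#'
#' The trace container is a tidy CSV with columns `time_s`, `channel`,
#' `value`; the sidecar JSON records the seed and all generator parameters so
#' any fixture can be regenerated exactly.
#'
#' @param channels Named list of numeric vectors (one per channel), all on
#'   the same grid.
#' @param time Time stamps in seconds.
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param meta Named list of metadata (seed, parameters, ...).
#' @return Invisibly, the CSV path.
#' @export
write_trials_csv <- function(channels, time, path, meta = list()) {
  stopifnot(is.list(channels), length(names(channels)) == length(channels))
  df <- do.call(rbind, lapply(names(channels), function(ch) {
    data.frame(time_s = time, channel = ch, value = channels[[ch]])
  }))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a tidy trial CSV back into named channels
#'
#' @param path CSV path written by [write_trials_csv()].
#' @return List with `time` and one numeric vector per channel; the sidecar
#'   metadata (if present) under `meta`.
#' @export
read_trials_csv <- function(path) {
  df <- read.csv(path)
  chans <- split(df, df$channel)
  out <- lapply(chans, function(d) d$value)
  out$time <- chans[[1]]$time_s
  side <- paste0(path, ".json")
  if (file.exists(side)) out$meta <- jsonlite::read_json(side)
  out
}

#' Write / read heading traces as tidy CSV
#'
#' Columns: `time_s`, `heading_deg`, `plume_azimuth_deg`, `fly_id`, `group`.
#'
#' @param traces List of `heading_trace` objects.
#' @param path CSV path.
#' @return `write_heading_csv`: invisibly the path. `read_heading_csv`: list
#'   of `heading_trace` objects.
#' @export
write_heading_csv <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(time_s = tr$time, heading_deg = tr$heading,
               plume_azimuth_deg = tr$plume_azimuth, fly_id = tr$fly_id,
               group = tr$group)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_heading_csv
#' @export
read_heading_csv <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$fly_id), function(d) {
    d <- d[order(d$time_s), ]
    heading_trace(d$time_s, d$heading_deg, d$plume_azimuth_deg[1],
                  fly_id = as.character(d$fly_id[1]),
                  group = as.character(d$group[1]))
  })
}

#' Read ROI fluorescence traces from tidy CSV
#'
#' Expects columns `time_s`, `roi_id`, `F` (optionally `fly_id`,
#' `cell_type`).
#'
#' @param path CSV path.
#' @return List of `roi_trace` objects, one per `roi_id`.
#' @export
read_roi_csv <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$roi_id), function(d) {
    d <- d[order(d$time_s), ]
    roi_trace(d$time_s, d$F, roi_id = as.character(d$roi_id[1]),
              fly_id = if ("fly_id" %in% names(d))
                as.character(d$fly_id[1]) else "fly1",
              cell_type = if ("cell_type" %in% names(d))
                as.character(d$cell_type[1]) else NA_character_)
  })
}

#' Extract a mean-ROI trace from a multi-page TIFF stack
#'
#' Averages pixel values within a rectangular ROI on every page of a TIFF
#' stack. Requires the `tiff` package.
#'
#' @param path TIFF file path.
#' @param roi Integer vector `c(row0, row1, col0, col1)`, 0-based, half-open
#'   bounds.
#' @param frame_times Frame times in seconds; default a unit frame clock.
#' @param ... Passed to [roi_trace()].
#' @return An `roi_trace` of per-frame ROI means.
#' @export
read_roi_from_tiff <- function(path, roi, frame_times = NULL, ...) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_invalid("the 'tiff' package is required to read TIFF stacks")
  stopifnot(length(roi) == 4)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  rows <- (roi[1] + 1):roi[2]
  cols <- (roi[3] + 1):roi[4]
  f <- vapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    mean(p[rows, cols])
  }, numeric(1))
  if (is.null(frame_times)) frame_times <- seq_along(f) - 1
  roi_trace(frame_times, f, ...)
}
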