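## Derived per-track time series: ratiometric calcium ratio and speed.

#' Per-track calcium ratio traces
#'
#' The ratiometric indicator reports cytosolic calcium as the ratio of the
#' calcium-bound over the calcium-unbound channel intensity, independent of
#' dye load: `ratio = ca_bound / ca_unbound` at every timepoint.
#'
#' @param tracks A `track_table` from [read_tracks()] or [as_track_table()].
#' @return A `ca_traces` data.table with columns `run_id`, `condition`,
#'   `track_id`, `frame`, `time_s`, `ratio`, one row per timepoint.
#' @export
compute_ratio <- function(tracks) {
  stopifnot(inherits(tracks, "track_table"))
  out <- as.data.table(tracks)[
    , .(run_id, condition, track_id, frame, time_s,
        ratio = ca_bound / ca_unbound)]
  setattr(out, "params", attr(tracks, "params"))
  setattr(out, "class", c("ca_traces", class(out)))
  out[]
}

#' Per-track speed traces
#'
#' Instantaneous speed at frame `i` (for `i >= 1` within a track) is the
#' Euclidean 3D displacement from frame `i - 1` to `i` divided by the frame
#' interval, in um/min. The first frame of a track has no backward
#' displacement and is omitted, so speed traces are one timepoint shorter
#' than position traces. The smoothed speed is a trailing rolling mean of
#' the instantaneous speed over `speed_smoothing_window` available values
#' (2 timepoints = 20 s by default).
#'
#' @param tracks A `track_table`.
#' @param params An [acquisition_params()]; defaults to the parameters
#'   attached to `tracks`.
#' @return A `speed_traces` data.table with columns `run_id`, `condition`,
#'   `track_id`, `frame`, `time_s`, `speed_inst`, `speed_smooth`. Tracks with
#'   a single timepoint contribute no rows (with a warning).
#' @export
compute_speed <- function(tracks, params = attr(tracks, "params")) {
  stopifnot(inherits(tracks, "track_table"), inherits(params, "acquisition_params"))
  dt <- as.data.table(tracks)
  singles <- dt[, .N, by = .(run_id, track_id)][N < 2L]
  if (nrow(singles))
    warn_fmt("%d single-point track(s) yield empty speed traces", nrow(singles))
  w <- params$speed_smoothing_window
  out <- dt[, {
    if (.N < 2L) {
      .(frame = integer(0), time_s = numeric(0), condition = character(0),
        speed_inst = numeric(0), speed_smooth = numeric(0))
    } else {
      disp <- sqrt(diff(x_um)^2 + diff(y_um)^2 + diff(z_um)^2)
      dt_s <- diff(time_s)
      v <- disp / dt_s * 60
      .(frame = frame[-1L], time_s = time_s[-1L], condition = condition[-1L],
        speed_inst = v, speed_smooth = rolling_mean_trailing(v, w))
    }
  }, by = .(run_id, track_id)]
  setcolorder(out, c("run_id", "condition", "track_id", "frame", "time_s",
                     "speed_inst", "speed_smooth"))
  setattr(out, "params", params)
  setattr(out, "class", c("speed_traces", class(out)))
  out[]
}

#' Flat per-timepoint export (flow-cytometry-like table)
#'
#' Joins positions, calcium ratio, speeds, and an in-event indicator into one
#' row per (track, timepoint), suitable for gating-style downstream analysis
#' in flow-cytometry software.
#'
#' @param tracks A `track_table`.
#' @param traces Optional `ca_traces`; computed from `tracks` when `NULL`.
#' @param speeds Optional `speed_traces`; computed when `NULL`.
#' @param events Optional `event_set` from [detect_events()]; when supplied,
#'   the `in_event` column is `TRUE` exactly on frames inside an event span
#'   (trigger frame inclusive, release frame exclusive; incomplete events run
#'   to the end of the track), otherwise `FALSE`. Without `events` the column
#'   is `NA`.
#' @return A data.table with the track columns plus `ratio`, `speed_inst`,
#'   `speed_smooth`, `in_event`.
#' @export
export_timepoint_table <- function(tracks, traces = NULL, speeds = NULL,
                                   events = NULL) {
  stopifnot(inherits(tracks, "track_table"))
  traces <- traces %||% compute_ratio(tracks)
  speeds <- speeds %||% suppressWarnings(compute_speed(tracks))
  out <- as.data.table(tracks)
  check_ids <- function(x, label) {
    extra <- setdiff(unique(x$track_id), unique(out$track_id))
    if (length(extra))
      stop_fmt("consistency error: %s contain track id(s) absent from tracks: %s",
               label, paste(head(extra, 5L), collapse = ", "))
  }
  check_ids(traces, "traces")
  check_ids(speeds, "speeds")
  out <- merge(out,
               as.data.table(traces)[, .(run_id, track_id, frame, ratio)],
               by = c("run_id", "track_id", "frame"), all.x = TRUE)
  out <- merge(out,
               as.data.table(speeds)[, .(run_id, track_id, frame,
                                         speed_inst, speed_smooth)],
               by = c("run_id", "track_id", "frame"), all.x = TRUE)
  if (!is.null(events)) {
    ev <- event_table(events)
    check_ids(ev, "events")
    out[, in_event := FALSE]
    if (nrow(ev)) {
      last_frames <- out[, .(last_frame = max(frame)), by = .(run_id, track_id)]
      ev <- merge(ev, last_frames, by = c("run_id", "track_id"))
      for (i in seq_len(nrow(ev))) {
        hi <- if (ev$complete[i]) ev$end_frame[i] - 1L else ev$last_frame[i]
        out[run_id == ev$run_id[i] & track_id == ev$track_id[i] &
              frame >= ev$start_frame[i] & frame <= hi, in_event := TRUE]
      }
    }
  } else {
    out[, in_event := NA]
  }
  setorder(out, run_id, track_id, frame)
  setcolorder(out, c("run_id", "condition", "track_id", "frame", "time_s",
                     "x_um", "y_um", "z_um", "ca_bound", "ca_unbound",
                     "ratio", "speed_inst", "speed_smooth", "in_event"))
  out[]
}
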