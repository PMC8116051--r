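# Build small track tables / trace tables in code.

# one-track table from a ratio vector (stationary cell unless xyz given)
trace_track <- function(ratio, track_id = "t1", run_id = "r1",
                        condition = "selecting", dt = 10,
                        x = NULL, y = NULL, z = NULL, unbound = 1500) {
  n <- length(ratio)
  df <- data.frame(run_id = run_id, condition = condition,
                   track_id = track_id, frame = seq_len(n) - 1L,
                   x_um = x %||% rep(0, n), y_um = y %||% rep(0, n),
                   z_um = z %||% rep(0, n),
                   ca_bound = ratio * unbound, ca_unbound = unbound)
  as_track_table(df, acquisition_params(frame_interval_s = dt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stack several trace_track() tables into one table
stack_tracks <- function(...) {
  parts <- list(...)
  params <- attr(parts[[1L]], "params")
  as_track_table(data.table::rbindlist(parts), params)
}

# traces + speeds + events for a track table, with explicit background
run_detection <- function(tracks, background, ...) {
  det <- detection_params(background = background, ...)
  traces <- compute_ratio(tracks)
  speeds <- suppressWarnings(compute_speed(tracks))
  list(traces = traces, speeds = speeds,
       events = detect_events(traces, det), det = det)
}
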