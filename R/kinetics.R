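## Event-onset-aligned averaging and per-track pause-index statistics.

#' Align calcium and speed traces at event onset
#'
#' Shifts each signaling track so that the onset of its aligned event sits
#' at relative time 0 (the trigger timepoint, i.e. the initial calcium
#' rise), then averages ratio and speed across tracks at every relative
#' timepoint on the grid `[-window_pre_s, +window_post_s]`. Averaging is
#' ragged: a track contributes wherever it has data, and the per-timepoint
#' contributing-cell count is reported alongside mean and SD.
#'
#' @param traces A `ca_traces` table.
#' @param speeds A `speed_traces` table from the same track table.
#' @param events An `event_set` from [detect_events()].
#' @param window_pre_s Pre-onset context, seconds (>= 0; default 60).
#' @param window_post_s Post-onset extent, seconds (>= 0; default 600).
#' @param align `"first"` (default) aligns one event per track — the first,
#'   consistent with the duration statistics; `"all"` aligns every event.
#' @param speed_source `"smooth"` (default; the 2-timepoint averaged speed,
#'   as plotted in aligned-speed curves) or `"inst"`.
#' @return An `aligned_profile` data.table: `rel_time_s`, `mean_ratio`,
#'   `sd_ratio`, `n_cells`, `mean_speed`, `sd_speed`, `n_speed`. `n_cells`
#'   at `rel_time_s == 0` equals the number of aligned events.
#' @export
align_events <- function(traces, speeds, events,
                         window_pre_s = 60, window_post_s = 600,
                         align = c("first", "all"),
                         speed_source = c("smooth", "inst")) {
  align <- match.arg(align)
  speed_source <- match.arg(speed_source)
  stopifnot(window_pre_s >= 0, window_post_s >= 0)
  ev <- event_table(events)
  empty <- data.table(rel_time_s = numeric(0), mean_ratio = numeric(0),
                      sd_ratio = numeric(0), n_cells = integer(0),
                      mean_speed = numeric(0), sd_speed = numeric(0),
                      n_speed = integer(0))
  setattr(empty, "class", c("aligned_profile", class(empty)))
  if (!nrow(ev)) {
    warn_fmt("no signaling tracks; empty aligned profile")
    return(empty[])
  }
  onsets <- if (align == "first") {
    ev[order(start_time_s), .SD[1L], by = .(run_id, track_id)]
  } else ev
  tr <- as.data.table(traces)
  sp <- as.data.table(speeds)
  sp[, speed := if (speed_source == "smooth") speed_smooth else speed_inst]

  gather <- function(dt, valcol) {
    pieces <- lapply(seq_len(nrow(onsets)), function(i) {
      d <- dt[run_id == onsets$run_id[i] & track_id == onsets$track_id[i]]
      rel <- d$time_s - onsets$start_time_s[i]
      keep <- rel >= -window_pre_s & rel <= window_post_s
      data.table(rel_time_s = rel[keep], value = d[[valcol]][keep])
    })
    rbindlist(pieces)
  }
  rat <- gather(tr, "ratio")[, .(m = mean(value),
                                 s = sd(value), n = .N), keyby = rel_time_s]
  spd <- gather(sp, "speed")[, .(ms = mean(value),
                                 ss = sd(value), ns = .N), keyby = rel_time_s]
  out <- merge(rat, spd, by = "rel_time_s", all = TRUE)
  setnames(out, c("m", "s", "n", "ms", "ss", "ns"),
           c("mean_ratio", "sd_ratio", "n_cells", "mean_speed", "sd_speed",
             "n_speed"))
  out[is.na(n_cells), n_cells := 0L]
  out[is.na(n_speed), n_speed := 0L]
  setorder(out, rel_time_s)
  setattr(out, "n_aligned", nrow(onsets))
  setattr(out, "class", c("aligned_profile", class(out)))
  out[]
}

#' Per-track pause index
#'
#' For each track containing at least one signaling event, classifies every
#' timepoint as signaling (inside an event span: trigger inclusive, release
#' exclusive; incomplete events extend to the end of the track) or
#' nonsignaling, averages the instantaneous (unsmoothed) speed over each
#' portion, and reports `pause_index = nonsignaling mean - signaling mean`
#' (um/min). A positive pause index indicates signal-associated migratory
#' pausing; it may legitimately be negative. Tracks that are entirely
#' signaling (or with no nonsignaling speed timepoint) are excluded with a
#' warning, as are tracks without events.
#'
#' @param speeds A `speed_traces` table.
#' @param events An `event_set` for the same tracks.
#' @return A `pause_records` data.table: `run_id`, `condition`, `track_id`,
#'   `n_signaling`, `n_nonsignaling`, `mean_speed_signaling`,
#'   `mean_speed_nonsignaling`, `pause_index`.
#' @export
pause_index <- function(speeds, events) {
  ev <- event_table(events)
  sp <- as.data.table(speeds)
  empty <- data.table(run_id = character(0), condition = character(0),
                      track_id = character(0), n_signaling = integer(0),
                      n_nonsignaling = integer(0),
                      mean_speed_signaling = numeric(0),
                      mean_speed_nonsignaling = numeric(0),
                      pause_index = numeric(0))
  if (!nrow(ev)) return(empty[])
  sig_tracks <- unique(ev[, .(run_id, track_id)])
  out <- vector("list", nrow(sig_tracks))
  n_excluded <- 0L
  for (i in seq_len(nrow(sig_tracks))) {
    rid <- sig_tracks$run_id[i]; tid <- sig_tracks$track_id[i]
    s <- sp[run_id == rid & track_id == tid]
    if (!nrow(s)) next
    e <- ev[run_id == rid & track_id == tid]
    in_ev <- rep(FALSE, nrow(s))
    for (j in seq_len(nrow(e))) {
      hi <- if (e$complete[j]) e$end_frame[j] - 1L else max(s$frame)
      in_ev <- in_ev | (s$frame >= e$start_frame[j] & s$frame <= hi)
    }
    if (!any(in_ev) || all(in_ev)) {
      n_excluded <- n_excluded + 1L
      next
    }
    out[[i]] <- data.table(
      run_id = rid, condition = s$condition[1L], track_id = tid,
      n_signaling = sum(in_ev), n_nonsignaling = sum(!in_ev),
      mean_speed_signaling = mean(s$speed_inst[in_ev]),
      mean_speed_nonsignaling = mean(s$speed_inst[!in_ev]))
  }
  if (n_excluded)
    warn_fmt("pause index undefined for %d track(s) lacking both signaling and nonsignaling speed timepoints; excluded",
             n_excluded)
  res <- rbindlist(out[!vapply(out, is.null, logical(1L))])
  if (!nrow(res)) return(empty[])
  res[, pause_index := mean_speed_nonsignaling - mean_speed_signaling]
  res[order(run_id, track_id)][]
}

#' Per-condition kinetic summary table
#'
#' Recomputes, within each condition, the headline statistics of a detection
#' run: number of tracks and signaling tracks, mean and SD of
#' first-complete-event durations, mean and SD of pause indices, merged
#' event frequency, and the fraction of elevated timepoints. SDs (not SEMs)
#' are reported, with the contributing n exposed so either can be derived.
#'
#' @param traces A `ca_traces` table.
#' @param speeds The matching `speed_traces`.
#' @param events The matching `event_set`.
#' @param params A [detection_params()]; defaults to the one stored in
#'   `events`.
#' @return A data.table with one row per condition, ordered by condition
#'   name.
#' @export
summarize_kinetics <- function(traces, speeds, events,
                               params = attr(events, "params")) {
  tr <- as.data.table(traces)
  conds <- sort(unique(tr$condition))
  if (!length(conds)) {
    return(data.table(condition = character(0)))
  }
  tracks_all <- attr(events, "tracks")
  ev <- event_table(events)
  pe <- percent_elevated_timepoints(traces, params)
  rows <- lapply(conds, function(cc) {
    sub_tracks <- tracks_all[condition == cc]
    sub_ev <- ev[condition == cc]
    sub <- copy(sub_ev)
    setattr(sub, "tracks", sub_tracks)
    setattr(sub, "params", params)
    setattr(sub, "class", c("event_set", class(sub)))
    dur <- first_complete_event_durations(sub)
    pr <- suppressWarnings(
      pause_index(as.data.table(speeds)[condition == cc], sub))
    fr <- event_frequency(sub, params)
    data.table(condition = cc,
               n_tracks = nrow(sub_tracks),
               n_signaling_tracks = uniqueN(sub_ev[, .(run_id, track_id)]),
               n_complete_first_events = nrow(dur),
               mean_duration_s = if (nrow(dur)) mean(dur$duration_s) else NA_real_,
               sd_duration_s = if (nrow(dur) > 1L) sd(dur$duration_s) else NA_real_,
               n_pause = nrow(pr),
               mean_pause_index = if (nrow(pr)) mean(pr$pause_index) else NA_real_,
               sd_pause_index = if (nrow(pr) > 1L) sd(pr$pause_index) else NA_real_,
               events_per_min = fr$events_per_min,
               min_per_event = fr$min_per_event,
               pct_elevated = unname(pe[cc]))
  })
  rbindlist(rows)[]
}
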