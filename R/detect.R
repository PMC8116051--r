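## Hysteresis segmentation of calcium signaling events and the associated
## duration, percent-signaling, and frequency statistics.

#' Event-detection parameters
#'
#' Hysteresis thresholding above the background calcium ratio `B` (the mean
#' ratio under nonselecting conditions; 0.675 in the reference data): a cell
#' is signaling when its ratio is at least `delta_high` above `B` for at
#' least `min_consecutive` consecutive timepoints, and the event ends at the
#' first of `min_consecutive` consecutive timepoints back below
#' `B + delta_low`. The two-level (trigger high, release low) rule
#' suppresses chatter around a single threshold. For the event-frequency
#' statistic, events separated by less than `quiescence_gap_s` of
#' nonsignaling are merged into one counted event.
#'
#' @param background Background ratio `B`; supply a number, or `NULL` to
#'   require an explicit value / [estimate_background()] result at call
#'   sites. May also be a named numeric vector keyed by run id (per-run
#'   backgrounds).
#' @param delta_high Trigger offset above `B` (default 0.2).
#' @param delta_low Release offset above `B` (default 0.1); must satisfy
#'   `delta_high > delta_low > 0`.
#' @param min_consecutive Persistence, in timepoints, required for both the
#'   trigger and the release (default 2; must be >= 2).
#' @param quiescence_gap_s Minimum nonsignaling period, in seconds, that
#'   separates counted frequency events (default 240 s = 4 min).
#' @param smooth_window Optional trailing rolling-mean window (timepoints)
#'   applied to the ratio before thresholding; default 1 (raw ratios).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(background = NULL, delta_high = 0.2,
                             delta_low = 0.1, min_consecutive = 2L,
                             quiescence_gap_s = 240, smooth_window = 1L) {
  if (!is_number(delta_high, min = 0) || !is_number(delta_low, min = 0) ||
      delta_high <= delta_low)
    stop_fmt("invalid detection params: require delta_high > delta_low > 0 (got %s, %s)",
             format(delta_high), format(delta_low))
  if (!is_count(min_consecutive, min = 2L))
    stop_fmt("invalid detection params: min_consecutive must be an integer >= 2")
  if (!is_number(quiescence_gap_s, min = 0))
    stop_fmt("invalid detection params: quiescence_gap_s must be > 0")
  if (!is_count(smooth_window, min = 1L))
    stop_fmt("invalid detection params: smooth_window must be an integer >= 1")
  if (!is.null(background) &&
      (!is.numeric(background) || any(!is.finite(background)) || any(background < 0)))
    stop_fmt("invalid detection params: background must be finite and >= 0")
  structure(list(background = background,
                 delta_high = as.numeric(delta_high),
                 delta_low = as.numeric(delta_low),
                 min_consecutive = as.integer(min_consecutive),
                 quiescence_gap_s = as.numeric(quiescence_gap_s),
                 smooth_window = as.integer(smooth_window)),
            class = "detection_params")
}

#' Estimate the background calcium ratio from nonselecting tracks
#'
#' The background is the mean ratio over all timepoints of all tracks imaged
#' under nonselecting conditions (tissue lacking the restricting MHC), where
#' TCR-driven calcium flux is absent.
#'
#' @param traces A `ca_traces` table ([compute_ratio()]); only rows with
#'   `condition == "nonselecting"` are used.
#' @param scope `"pooled"` (one value across all runs; the default, matching
#'   the single published reference value) or `"per_run"` (a named vector of
#'   per-run means, for run-wise background subtraction).
#' @return A single number (`pooled`) or a named numeric vector (`per_run`).
#' @export
estimate_background <- function(traces, scope = c("pooled", "per_run")) {
  scope <- match.arg(scope)
  dt <- as.data.table(traces)[condition == "nonselecting"]
  if (!nrow(dt))
    stop_fmt("background estimation error: no nonselecting traces; supply the background ratio explicitly")
  if (scope == "pooled") {
    mean(dt$ratio)
  } else {
    agg <- dt[, .(B = mean(ratio)), keyby = run_id]
    setNames(agg$B, agg$run_id)
  }
}

## Core scanner on one numeric ratio vector. Returns integer matrix with
## columns start, end (NA if truncated), 1-based indices into r.
## Scan left to right: an event starts at the first of >= nmin consecutive
## values >= thr_high; once triggered it ends at the first of nmin
## consecutive values < thr_low (or at the end of the trace, incomplete);
## scanning resumes after the release run.
hysteresis_scan <- function(r, thr_high, thr_low, nmin) {
  n <- length(r)
  trig_len <- consecutive_run_length(r >= thr_high)
  rel_len <- consecutive_run_length(r < thr_low)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    cand <- which(trig_len[i:n] >= nmin)
    if (!length(cand)) break
    s <- i + cand[1L] - 1L
    rel <- if (s < n) which(rel_len[(s + 1L):n] >= nmin) else integer(0)
    if (!length(rel)) {
      starts <- c(starts, s); ends <- c(ends, NA_integer_)
      break
    }
    e <- s + rel[1L]
    starts <- c(starts, s); ends <- c(ends, e)
    i <- e + nmin
  }
  cbind(start = starts, end = ends)
}

track_background <- function(params, run) {
  B <- params$background
  if (is.null(B))
    stop_fmt("background ratio not set; pass detection_params(background = ...) or estimate_background()")
  if (length(B) == 1L && is.null(names(B))) return(as.numeric(B))
  if (!run %in% names(B))
    stop_fmt("no background value for run '%s'", run)
  as.numeric(B[[run]])
}

#' Detect calcium signaling events on every track
#'
#' Applies the hysteresis trigger/release rules of
#' [detection_params()] to each track's ratio trace. An event starts at the
#' first of `min_consecutive` consecutive timepoints with
#' `ratio >= B + delta_high` (values exactly at the threshold count as
#' high); once triggered it ends at the first of `min_consecutive`
#' consecutive timepoints with `ratio < B + delta_low` — the event's
#' `end_frame` is that first returned timepoint, so the signaling span is
#' the half-open `[start_frame, end_frame)` and
#' `duration_s = end_time - start_time`. A track that finishes while still
#' signaling yields an event with `complete = FALSE` and no end or duration.
#'
#' @param traces A `ca_traces` table.
#' @param params A [detection_params()] with a non-`NULL` background.
#' @return An `event_set`: a data.table of events (`run_id`, `condition`,
#'   `track_id`, `start_frame`, `end_frame`, `complete`, `start_time_s`,
#'   `end_time_s`, `duration_s`) with attributes `tracks` (per-track frame
#'   counts and durations over all input tracks, signaling or not) and
#'   `params`.
#' @export
detect_events <- function(traces, params) {
  stopifnot(inherits(params, "detection_params"))
  dt <- as.data.table(traces)
  if (any(!is.finite(dt$ratio)))
    stop_fmt("validation error: non-finite ratio values in traces")
  nmin <- params$min_consecutive
  ev <- dt[, {
    B <- track_background(params, run_id[1L])
    r <- if (params$smooth_window > 1L)
      rolling_mean_trailing(ratio, params$smooth_window) else ratio
    m <- hysteresis_scan(r, B + params$delta_high, B + params$delta_low, nmin)
    if (nrow(m)) {
      comp <- !is.na(m[, "end"])
      .(condition = condition[1L],
        start_frame = frame[m[, "start"]],
        end_frame = ifelse(comp, frame[m[, "end"]], NA_integer_),
        complete = comp,
        start_time_s = time_s[m[, "start"]],
        end_time_s = ifelse(comp, time_s[m[, "end"]], NA_real_))
    } else {
      .(condition = character(0), start_frame = integer(0),
        end_frame = integer(0), complete = logical(0),
        start_time_s = numeric(0), end_time_s = numeric(0))
    }
  }, by = .(run_id, track_id)]
  ev[, duration_s := end_time_s - start_time_s]
  setcolorder(ev, c("run_id", "condition", "track_id", "start_frame",
                    "end_frame", "complete", "start_time_s", "end_time_s",
                    "duration_s"))
  track_summary <- dt[, .(condition = condition[1L], n_frames = .N,
                          t_first = min(time_s), t_last = max(time_s),
                          duration_s = max(time_s) - min(time_s)),
                      by = .(run_id, track_id)]
  setattr(ev, "tracks", track_summary)
  setattr(ev, "params", params)
  setattr(ev, "class", c("event_set", class(ev)))
  ev[]
}

## coerce event_set (or plain event data.table) to a data.table of events
event_table <- function(events) {
  stopifnot(is.data.frame(events))
  as.data.table(events)
}

#' Cumulative track imaging time
#'
#' Sum of the track durations (last minus first timepoint, seconds) over all
#' tracks compiled into an `event_set`, signaling or not.
#'
#' @param events An `event_set` from [detect_events()].
#' @return Total time in seconds.
#' @export
cumulative_track_time_s <- function(events) {
  tr <- attr(events, "tracks")
  if (is.null(tr)) stop_fmt("events carry no track summary; use detect_events()")
  sum(tr$duration_s)
}

#' Duration of each track's first complete event
#'
#' Only events with a defined beginning and end enter duration statistics,
#' and only the first signaling event of each track is used; a track whose
#' first event is incomplete contributes nothing.
#'
#' @param events An `event_set`.
#' @return A data.table with `run_id`, `condition`, `track_id`,
#'   `duration_s`, one row per contributing track.
#' @export
first_complete_event_durations <- function(events) {
  ev <- event_table(events)
  if (!nrow(ev))
    return(data.table(run_id = character(0), condition = character(0),
                      track_id = character(0), duration_s = numeric(0)))
  first <- ev[order(start_frame), .SD[1L], by = .(run_id, track_id)]
  first[complete == TRUE,
        .(run_id, condition, track_id, duration_s)][order(run_id, track_id)]
}

#' Fraction of timepoints with elevated calcium, per condition
#'
#' A timepoint is elevated when its ratio is at least `delta_high` above the
#' background; this per-timepoint classification carries no persistence
#' requirement (persistence applies to events, not to this summary metric).
#'
#' @param traces A `ca_traces` table covering one or more conditions.
#' @param params A [detection_params()] with a non-`NULL` background.
#' @return Named numeric vector of fractions in `[0, 1]`, one per condition
#'   present in `traces`, ordered by condition name.
#' @export
percent_elevated_timepoints <- function(traces, params) {
  stopifnot(inherits(params, "detection_params"))
  dt <- as.data.table(traces)
  if (!nrow(dt)) {
    warn_fmt("no traces supplied; empty result")
    return(setNames(numeric(0), character(0)))
  }
  agg <- dt[, {
    thr <- vapply(run_id, function(rr) track_background(params, rr),
                  numeric(1L)) + params$delta_high
    .(frac = mean(ratio >= thr))
  }, keyby = condition]
  setNames(agg$frac, agg$condition)
}

#' Signaling-event frequency over cumulative track time
#'
#' Counts events for the frequency statistic: hysteresis events on the same
#' track separated by less than `quiescence_gap_s` of nonsignaling (release
#' to next trigger) are merged into one counted event, and by default track
#' start/end act as bounding quiescence so boundary-truncated events still
#' count. The frequency is the merged-event count divided by the cumulative
#' track imaging time over all compiled tracks.
#'
#' @param events An `event_set` from [detect_events()].
#' @param params A [detection_params()]; defaults to the parameters stored
#'   in `events`.
#' @param boundary_quiescence If `TRUE` (default), the beginning and end of
#'   a track bound an event like a quiescent period does; if `FALSE`, only
#'   complete events preceded and followed by at least `quiescence_gap_s`
#'   of recorded nonsignaling are counted.
#' @return A list with `n_events` (raw hysteresis events), `n_counted`
#'   (after merging), `cumulative_track_time_min`, `events_per_min`, and
#'   `min_per_event` (reciprocal; `Inf` when no events).
#' @export
event_frequency <- function(events, params = attr(events, "params"),
                            boundary_quiescence = TRUE) {
  stopifnot(inherits(params, "detection_params"))
  ev <- event_table(events)
  total_s <- cumulative_track_time_s(events)
  if (total_s <= 0) stop_fmt("arithmetic error: cumulative track time is zero")
  gap_s <- params$quiescence_gap_s
  if (!nrow(ev)) {
    return(list(n_events = 0L, n_counted = 0L,
                cumulative_track_time_min = total_s / 60,
                events_per_min = 0, min_per_event = Inf))
  }
  tr <- attr(events, "tracks")
  ev <- merge(ev, tr[, .(run_id, track_id, t_first, t_last)],
              by = c("run_id", "track_id"))
  per_track <- ev[order(start_time_s), {
    ## merge events separated by < gap_s of nonsignaling into groups
    new_group <- rep(TRUE, .N)
    if (.N > 1L) {
      gaps <- start_time_s[-1L] - end_time_s[-.N]
      new_group[-1L] <- is.na(gaps) | gaps >= gap_s
    }
    grp <- cumsum(new_group)
    n_grp <- max(grp)
    if (boundary_quiescence) {
      n_merged <- n_grp
    } else {
      ## track boundaries do not count: a merged event needs >= gap_s of
      ## recorded nonsignaling before its start and after its (defined) end
      ok <- vapply(seq_len(n_grp), function(g) {
        gs <- min(start_time_s[grp == g])
        ge <- if (anyNA(end_time_s[grp == g])) NA_real_
              else max(end_time_s[grp == g])
        lead_ok <- if (g > 1L) TRUE else (gs - t_first[1L]) >= gap_s
        trail_ok <- if (g < n_grp) TRUE else
          !is.na(ge) && (t_last[1L] - ge) >= gap_s
        lead_ok && trail_ok && !is.na(ge)
      }, logical(1L))
      n_merged <- sum(ok)
    }
    .(n_raw = .N, n_counted = n_merged)
  }, by = .(run_id, track_id)]
  n_counted <- sum(per_track$n_counted)
  total_min <- total_s / 60
  list(n_events = sum(per_track$n_raw),
       n_counted = n_counted,
       cumulative_track_time_min = total_min,
       events_per_min = n_counted / total_min,
       min_per_event = if (n_counted > 0) total_min / n_counted else Inf)
}
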