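## Track tables: per-timepoint spot records for many cells across runs and
## selecting/nonselecting conditions, as exported by spot-tracking software.

TRACK_COLUMNS <- c("run_id", "condition", "track_id", "frame",
                   "x_um", "y_um", "z_um", "ca_bound", "ca_unbound")

CONDITIONS <- c("selecting", "nonselecting")

#' Acquisition parameters
#'
#' Time base and smoothing window of the imaging run. Frames are collected
#' every `frame_interval_s` seconds (10 s in the reference acquisitions) and
#' speeds are reported both instantaneous and as a trailing rolling mean over
#' `speed_smoothing_window` timepoints (2 timepoints = 20 s by default).
#'
#' @param frame_interval_s Seconds per frame; must be > 0.
#' @param speed_smoothing_window Integer number of trailing timepoints
#'   averaged for the smoothed speed; must be >= 1. A window of 1 leaves the
#'   instantaneous speed unchanged.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(frame_interval_s = 10,
                               speed_smoothing_window = 2L) {
  if (!is_number(frame_interval_s, min = 0))
    stop_fmt("frame_interval_s must be a single number > 0")
  if (!is_count(speed_smoothing_window, min = 1L))
    stop_fmt("speed_smoothing_window must be an integer >= 1")
  structure(list(frame_interval_s = as.numeric(frame_interval_s),
                 speed_smoothing_window = as.integer(speed_smoothing_window)),
            class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf("acquisition: %g s/frame, speed smoothing over %d timepoints\n",
              x$frame_interval_s, x$speed_smoothing_window))
  invisible(x)
}

## split tracks at frame gaps larger than one interval; fragments become
## tracks in their own right (suffix .1, .2, ...). Tracks without gaps keep
## their ids untouched.
split_track_gaps <- function(dt) {
  dt[, fragment := cumsum(c(0L, diff(frame) > 1L)), by = .(run_id, track_id)]
  n_frag <- dt[, .(nf = max(fragment) + 1L), by = .(run_id, track_id)]
  if (any(n_frag$nf > 1L)) {
    dt[n_frag[nf > 1L], on = c("run_id", "track_id"),
       track_id := paste0(track_id, ".", fragment + 1L)]
  }
  dt[, fragment := NULL]
  dt
}

#' Build a validated track table from a data frame
#'
#' Validates the per-timepoint schema (see `read_tracks()` for columns),
#' sorts rows by (run, track, frame), fills `time_s` from
#' `frame * frame_interval_s` when absent, and splits tracks at frame gaps
#' larger than one interval (each contiguous fragment becomes its own track;
#' the tracker is expected to emit contiguous tracks, so a gap indicates a
#' dropped spot and must not contribute a spurious large displacement).
#'
#' @param df A data.frame with the track-table columns.
#' @param params An [acquisition_params()] object.
#' @return A `track_table` (data.table) with the acquisition parameters
#'   attached as attribute `"params"`.
#' @export
as_track_table <- function(df, params = acquisition_params()) {
  stopifnot(inherits(params, "acquisition_params"))
  missing <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing))
    stop_fmt("track table format error: missing column(s) %s",
             paste(missing, collapse = ", "))
  dt <- as.data.table(df)
  dt[, `:=`(run_id = as.character(run_id),
            condition = as.character(condition),
            track_id = as.character(track_id),
            frame = as.integer(frame))]
  num_cols <- c("x_um", "y_um", "z_um", "ca_bound", "ca_unbound")
  for (cc in num_cols) set(dt, j = cc, value = as.numeric(dt[[cc]]))

  bad_cond <- setdiff(unique(dt$condition), CONDITIONS)
  if (length(bad_cond))
    stop_fmt("validation error: condition must be one of {%s}; found %s",
             paste(CONDITIONS, collapse = ", "),
             paste(bad_cond, collapse = ", "))
  bad <- which(!is.finite(dt$ca_unbound) | dt$ca_unbound <= 0)
  if (length(bad))
    stop_fmt("validation error: nonpositive ca_unbound at row(s) %s",
             paste(head(bad, 5L), collapse = ", "))
  bad <- which(!is.finite(dt$ca_bound) | dt$ca_bound < 0)
  if (length(bad))
    stop_fmt("validation error: negative or non-finite ca_bound at row(s) %s",
             paste(head(bad, 5L), collapse = ", "))
  if (anyNA(dt$frame) || any(dt$frame < 0L))
    stop_fmt("validation error: frame must be a nonnegative integer")

  setorder(dt, run_id, track_id, frame)
  dup <- dt[, .N, by = .(run_id, track_id, frame)][N > 1L]
  if (nrow(dup))
    stop_fmt("validation error: duplicate (track, frame) pairs, first at track %s frame %d",
             dup$track_id[1L], dup$frame[1L])
  multi_cond <- dt[, uniqueN(condition), by = .(run_id, track_id)][V1 > 1L]
  if (nrow(multi_cond))
    stop_fmt("validation error: track %s has more than one condition",
             multi_cond$track_id[1L])

  dt <- split_track_gaps(dt)
  if (!"time_s" %in% names(dt)) {
    dt[, time_s := frame * params$frame_interval_s]
  } else {
    dt[, time_s := as.numeric(time_s)]
    dt[is.na(time_s), time_s := frame * params$frame_interval_s]
  }
  setcolorder(dt, c("run_id", "condition", "track_id", "frame", "time_s",
                    "x_um", "y_um", "z_um", "ca_bound", "ca_unbound"))
  setattr(dt, "params", params)
  setattr(dt, "class", c("track_table", class(dt)))
  dt[]
}

#' Read a cell-track table from delimited text
#'
#' Expects a header naming at least the columns `run_id`, `condition`,
#' `track_id`, `frame`, `x_um`, `y_um`, `z_um`, `ca_bound`, `ca_unbound`
#' (`time_s` optional; filled from `frame * frame_interval_s` when absent).
#' One row per (track, frame). Comma- or tab-delimited files are detected
#' automatically.
#'
#' @inheritParams as_track_table
#' @param path Path to the delimited-text file.
#' @return A validated `track_table`; see [as_track_table()].
#' @export
read_tracks <- function(path, params = acquisition_params()) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  dt <- fread(path, colClasses = list(character = intersect(
    c("run_id", "condition", "track_id"),
    names(fread(path, nrows = 0L)))))
  as_track_table(dt, params)
}

#' Write a track table (or any derived table) as delimited text
#'
#' @param x A data.frame / `track_table`.
#' @param path Output path; format is CSV.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(x, path) {
  fwrite(as.data.table(x), path)
  invisible(path)
}

#' Read a spot-tracking-software export dialect
#'
#' Compatibility reader for trackers that export position and the two
#' calcium-channel intensities as separate sheets keyed by track id and
#' time index (the Imaris convention). Maps the three files onto the
#' canonical track-table schema.
#'
#' @param position_path Delimited text with columns `TrackID`, `Time`,
#'   `Position X`, `Position Y`, `Position Z` (any delimiter `fread`
#'   understands; column name matching is case- and punctuation-insensitive).
#' @param bound_path,unbound_path Per-channel mean-intensity sheets with
#'   columns `TrackID`, `Time`, `Intensity`.
#' @param run_id,condition Run label and condition (`"selecting"` or
#'   `"nonselecting"`) to assign to every track in the files.
#' @param params An [acquisition_params()] object. `Time` is interpreted as a
#'   1-based frame index (the tracker convention) and converted to 0-based
#'   frames.
#' @return A validated `track_table`.
#' @export
read_imaris_export <- function(position_path, bound_path, unbound_path,
                               run_id, condition,
                               params = acquisition_params()) {
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  pick <- function(dt, want, label) {
    hit <- which(norm(names(dt)) == norm(want))
    if (!length(hit))
      stop_fmt("format error: column '%s' not found in %s sheet", want, label)
    dt[[hit[1L]]]
  }
  pos <- fread(position_path)
  bnd <- fread(bound_path)
  unb <- fread(unbound_path)
  base <- data.table(track_id = as.character(pick(pos, "TrackID", "position")),
                     frame = as.integer(pick(pos, "Time", "position")) - 1L,
                     x_um = as.numeric(pick(pos, "PositionX", "position")),
                     y_um = as.numeric(pick(pos, "PositionY", "position")),
                     z_um = as.numeric(pick(pos, "PositionZ", "position")))
  chan <- function(dt, label) {
    data.table(track_id = as.character(pick(dt, "TrackID", label)),
               frame = as.integer(pick(dt, "Time", label)) - 1L,
               value = as.numeric(pick(dt, "Intensity", label)))
  }
  b <- chan(bnd, "bound channel"); setnames(b, "value", "ca_bound")
  u <- chan(unb, "unbound channel"); setnames(u, "value", "ca_unbound")
  out <- base[b, on = c("track_id", "frame")][u, on = c("track_id", "frame")]
  if (anyNA(out$x_um))
    stop_fmt("consistency error: channel sheets contain (track, time) keys absent from the position sheet")
  out[, `:=`(run_id = as.character(run_id), condition = as.character(condition))]
  as_track_table(out, params)
}
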