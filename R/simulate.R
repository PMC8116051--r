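## Synthetic cell tracks with ground-truth calcium events and motility, and
## expression matrices with planted signatures. The generator emulates the
## structure of two-photon thymocyte imaging data: persistent-random-walk
## motility, a baseline bound/unbound ratio near 0.675 with Gaussian noise,
## Poisson-arriving square calcium transients, and a speed drop while
## signaling.

#' Track-simulation parameters
#'
#' Defaults encode the reference acquisition and the published magnitudes:
#' 10 s frames, baseline ratio 0.675, one event per 75 min, ~4 min events
#' bounded by a 4 min refractory period, and a 3 um/min in-event speed drop
#' on a ~6 um/min walker.
#'
#' @param n_tracks Number of tracks.
#' @param duration_s Track length in seconds (default 1200 = 20 min).
#' @param frame_interval_s Seconds per frame (default 10).
#' @param baseline_ratio Baseline calcium ratio `B0` (default 0.675).
#' @param ratio_noise_sd Gaussian noise SD on the ratio (default 0.03).
#' @param event_rate_per_min Poisson intensity of event onsets (default
#'   1/75 per minute).
#' @param event_duration_mean_s,event_duration_sd_s Event duration is drawn
#'   Normal(mean, sd), floored at two frames and rounded to whole frames
#'   (defaults 240 s and 60 s).
#' @param event_shape `"square"` (default; full amplitude on every in-event
#'   frame, keeping ground truth unambiguous) or `"rise_decay"` (one-frame
#'   rise to full amplitude, then exponential decay with time constant half
#'   the event duration — closer to real transients, but with a soft end).
#' @param event_amplitude Ratio units added above baseline during an event
#'   (default 0.3); a warning is emitted when the amplitude is at or below
#'   the 0.2 trigger offset, where events are undetectable by construction.
#' @param refractory_s Minimum separation between event onsets and between
#'   one event's end and the next onset (default 240 s).
#' @param speed_base_um_min Mean step speed outside events (default 6).
#' @param speed_sd_um_min Per-step speed SD (default 1.5); speeds are
#'   floored at 0.
#' @param speed_drop_um_min Reduction of mean step speed during events
#'   (default 3).
#' @param motility_persistence Directional persistence in `[0, 1]`: each
#'   step's direction is the normalized blend
#'   `p * previous + (1 - p) * random` (default 0.6).
#' @param run_id,condition Labels stamped on every generated track.
#' @param seed Optional integer seed; when supplied, the generator is fully
#'   reproducible (a single stream drives, in order: per-track start
#'   positions, event arrivals, durations, ratio noise, step speeds, and
#'   directions, track by track).
#' @return An object of class `track_sim_params`.
#' @export
track_sim_params <- function(n_tracks = 100L, duration_s = 1200,
                             frame_interval_s = 10,
                             baseline_ratio = 0.675, ratio_noise_sd = 0.03,
                             event_rate_per_min = 1 / 75,
                             event_duration_mean_s = 240,
                             event_duration_sd_s = 60,
                             event_shape = c("square", "rise_decay"),
                             event_amplitude = 0.3, refractory_s = 240,
                             speed_base_um_min = 6, speed_sd_um_min = 1.5,
                             speed_drop_um_min = 3,
                             motility_persistence = 0.6,
                             run_id = "sim", condition = "selecting",
                             seed = NULL) {
  event_shape <- match.arg(event_shape)
  stopifnot(is_count(n_tracks, 1L), is_number(duration_s, 0),
            is_number(frame_interval_s, 0),
            is_number(baseline_ratio, 0), ratio_noise_sd >= 0,
            event_rate_per_min >= 0, is_number(event_duration_mean_s, 0),
            event_duration_sd_s >= 0, event_amplitude > 0,
            is_number(refractory_s, 0), is_number(speed_base_um_min, 0),
            speed_sd_um_min >= 0, speed_drop_um_min >= 0,
            motility_persistence >= 0, motility_persistence <= 1,
            condition %in% CONDITIONS)
  structure(as.list(environment()), class = "track_sim_params")
}

random_unit_vector <- function() {
  v <- rnorm(3L)
  v / sqrt(sum(v^2))
}

## Poisson arrivals on [0, T) thinned so that consecutive events are
## separated by >= refractory_s after the previous event's end.
sample_event_spans <- function(p, n_frames) {
  t_total <- (n_frames - 1L) * p$frame_interval_s
  rate_s <- p$event_rate_per_min / 60
  if (rate_s <= 0 || t_total <= 0)
    return(data.table(start_frame = integer(0), end_frame = integer(0),
                      truncated = logical(0)))
  n_arr <- stats::rpois(1L, rate_s * t_total)
  onsets <- sort(runif(n_arr, 0, t_total))
  starts <- integer(0); ends <- integer(0); trunc <- logical(0)
  prev_end_s <- -Inf
  for (t0 in onsets) {
    if (t0 < prev_end_s + p$refractory_s) next  ## thinned by refractoriness
    dur_s <- max(2 * p$frame_interval_s,
                 rnorm(1L, p$event_duration_mean_s, p$event_duration_sd_s))
    s_f <- as.integer(round(t0 / p$frame_interval_s))
    e_f <- s_f + as.integer(round(dur_s / p$frame_interval_s))
    if (s_f > n_frames - 1L) next
    truncated <- e_f > n_frames - 1L
    if (truncated) e_f <- n_frames  ## in-event through the last frame
    if (length(starts) && s_f < ends[length(ends)] +
          as.integer(round(p$refractory_s / p$frame_interval_s))) next
    starts <- c(starts, s_f); ends <- c(ends, e_f)
    trunc <- c(trunc, truncated)
    prev_end_s <- e_f * p$frame_interval_s
  }
  data.table(start_frame = starts, end_frame = ends, truncated = trunc)
}

event_shape_profile <- function(p, spans, n_frames) {
  ## amplitude multiplier per frame (0 outside events)
  prof <- numeric(n_frames)
  for (j in seq_len(nrow(spans))) {
    idx <- (spans$start_frame[j]:(spans$end_frame[j] - 1L)) + 1L
    if (p$event_shape == "square") {
      prof[idx] <- 1
    } else {
      k <- seq_along(idx) - 1L
      tau <- max(1, length(idx) / 2)
      prof[idx] <- exp(-k / tau)
      prof[idx[1L]] <- 1
    }
  }
  prof
}

#' Simulate cell tracks with ground-truth calcium events
#'
#' Generates a `track_table` in the canonical schema together with the
#' ground truth used to produce it. Positions follow a 3D persistent random
#' walk whose per-step speed is drawn around `speed_base_um_min`, reduced by
#' `speed_drop_um_min` on in-event steps; event onsets arrive as a Poisson
#' process thinned by the refractory period; the ratio is
#' `B0 + amplitude * shape(t) + noise`, and the two fluorescence channels
#' are emitted so that bound/unbound exactly equals the intended ratio.
#'
#' @param params A [track_sim_params()] object.
#' @return A list with elements `tracks` (a validated `track_table`),
#'   and `truth` (class `sim_ground_truth`): `events` (per-track injected
#'   spans with `truncated` flags), `flags` (per-timepoint in-event
#'   indicator), and the generating `params`.
#' @export
simulate_tracks <- function(params) {
  stopifnot(inherits(params, "track_sim_params"))
  p <- params
  if (p$event_rate_per_min > 0 && p$event_amplitude <= 0.2)
    warn_fmt("event amplitude %.3g is at or below the default 0.2 trigger offset; events may be undetectable",
             p$event_amplitude)
  if (!is.null(p$seed)) set.seed(p$seed)
  n_frames <- as.integer(floor(p$duration_s / p$frame_interval_s)) + 1L
  ids <- sprintf("t%04d", seq_len(p$n_tracks))
  rows <- vector("list", p$n_tracks)
  ev_list <- vector("list", p$n_tracks)
  flag_list <- vector("list", p$n_tracks)
  for (i in seq_len(p$n_tracks)) {
    pos0 <- c(runif(1L, 0, 200), runif(1L, 0, 200), runif(1L, 0, 50))
    spans <- sample_event_spans(p, n_frames)
    prof <- event_shape_profile(p, spans, n_frames)
    in_event <- prof > 0
    ratio <- p$baseline_ratio + p$event_amplitude * prof +
      rnorm(n_frames, 0, p$ratio_noise_sd)
    ratio <- pmax(ratio, 0.01)
    unbound <- rep(1500, n_frames)
    bound <- ratio * unbound
    ## persistent random walk; step into frame k feels frame k's event state
    xyz <- matrix(0, nrow = n_frames, ncol = 3L)
    xyz[1L, ] <- pos0
    dir <- random_unit_vector()
    if (n_frames > 1L) {
      for (k in 2:n_frames) {
        mu <- p$speed_base_um_min - p$speed_drop_um_min * in_event[k]
        v <- max(0, rnorm(1L, mu, p$speed_sd_um_min))     # um/min
        dir <- p$motility_persistence * dir +
          (1 - p$motility_persistence) * random_unit_vector()
        nrm <- sqrt(sum(dir^2))
        if (nrm < 1e-12) dir <- random_unit_vector() else dir <- dir / nrm
        xyz[k, ] <- xyz[k - 1L, ] + dir * v * p$frame_interval_s / 60
      }
    }
    rows[[i]] <- data.table(
      run_id = p$run_id, condition = p$condition, track_id = ids[i],
      frame = 0:(n_frames - 1L),
      x_um = xyz[, 1L], y_um = xyz[, 2L], z_um = xyz[, 3L],
      ca_bound = bound, ca_unbound = unbound)
    if (nrow(spans)) ev_list[[i]] <- data.table(track_id = ids[i], spans)
    flag_list[[i]] <- data.table(track_id = ids[i],
                                 frame = 0:(n_frames - 1L),
                                 in_event = in_event)
  }
  tracks <- as_track_table(rbindlist(rows),
                           acquisition_params(frame_interval_s = p$frame_interval_s))
  truth <- structure(
    list(events = rbindlist(ev_list[!vapply(ev_list, is.null, logical(1L))],
                            use.names = TRUE),
         flags = rbindlist(flag_list),
         params = p),
    class = "sim_ground_truth")
  if (!nrow(truth$events))
    truth$events <- data.table(track_id = character(0),
                               start_frame = integer(0),
                               end_frame = integer(0), truncated = logical(0))
  list(tracks = tracks, truth = truth)
}

#' Expression-simulation parameters
#'
#' Emulates the three-population microarray comparison (DN4 precursors,
#' preselection CD69- DP, and CD69+ DP progeny) with a log-normal baseline
#' intensity per gene, multiplicative log-normal replicate noise, and a
#' planted signature whose genes realize specified fold changes in the
#' CD69- DP population relative to both comparators.
#'
#' @param n_genes Size of the gene universe (default 1000).
#' @param groups Character vector of population labels (default `DN4`,
#'   `DP69neg`, `DP69pos`).
#' @param replicates Replicates per population (default 3; must be >= 2).
#' @param signature_genes Character vector of planted gene names (must be a
#'   subset of the generated universe `g0001..`, or new names to append).
#' @param signature_lfc Log2 fold change of planted genes in `DP69neg`
#'   versus each comparator (default 1.5).
#' @param signature_base Baseline (comparator) intensity of planted genes
#'   (default 1200 a.u., so that the three-population combined expression
#'   clears the 2000 a.u. filter at the default fold change).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   unplanted baseline intensities (defaults log(500) and 1).
#' @param noise_sdlog Multiplicative log-normal noise SD on every
#'   measurement (default 0.2); 0 gives the expectation-level matrix.
#' @param seed Optional integer seed.
#' @return An object of class `expr_sim_params`.
#' @export
expr_sim_params <- function(n_genes = 1000L,
                            groups = c("DN4", "DP69neg", "DP69pos"),
                            replicates = 3L,
                            signature_genes = character(0),
                            signature_lfc = 1.5,
                            signature_base = 1200,
                            baseline_meanlog = log(500),
                            baseline_sdlog = 1,
                            noise_sdlog = 0.2,
                            seed = NULL) {
  stopifnot(is_count(n_genes, 1L), is_count(replicates, 2L),
            is.character(groups), length(groups) >= 2L,
            is.numeric(signature_lfc), noise_sdlog >= 0,
            is_number(signature_base, 0))
  structure(as.list(environment()), class = "expr_sim_params")
}

#' Simulate a gene-by-sample expression matrix with a planted signature
#'
#' @param params An [expr_sim_params()] object.
#' @return A list with `expr` (numeric matrix, genes x samples), `samples`
#'   (data.table of `sample_id`, `population`, `replicate`), and `planted`
#'   (character vector of planted signature genes).
#' @export
simulate_expression <- function(params) {
  stopifnot(inherits(params, "expr_sim_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  genes <- sprintf("g%04d", seq_len(p$n_genes))
  planted <- unique(p$signature_genes)
  genes <- c(genes, setdiff(planted, genes))
  samples <- CJ(population = p$groups, replicate = seq_len(p$replicates),
                sorted = FALSE)
  samples[, sample_id := sprintf("%s_r%d", population, replicate)]
  base <- rlnorm(length(genes), p$baseline_meanlog, p$baseline_sdlog)
  names(base) <- genes
  base[planted] <- p$signature_base
  mu <- matrix(base, nrow = length(genes), ncol = nrow(samples),
               dimnames = list(genes, samples$sample_id))
  if (length(planted)) {
    lfc <- rep_len(p$signature_lfc, length(planted))
    target_cols <- samples$population == "DP69neg"
    mu[planted, target_cols] <- p$signature_base * 2^lfc
  }
  noise <- if (p$noise_sdlog > 0) {
    matrix(rlnorm(length(mu), meanlog = -p$noise_sdlog^2 / 2,
                  sdlog = p$noise_sdlog), nrow = nrow(mu))
  } else 1
  expr <- mu * noise
  list(expr = expr, samples = samples[], planted = planted)
}

#' Write an expression matrix and its annotation sidecar
#'
#' @param sim A list as returned by [simulate_expression()], or any list
#'   with `expr` and `samples` elements.
#' @param expr_path,samples_path Output CSV paths (gene-by-sample matrix
#'   with a leading `gene` column; sample annotation table).
#' @return `expr_path`, invisibly.
#' @export
write_expression <- function(sim, expr_path, samples_path) {
  m <- as.data.table(sim$expr, keep.rownames = "gene")
  fwrite(m, expr_path)
  fwrite(as.data.table(sim$samples), samples_path)
  invisible(expr_path)
}

#' Read an expression matrix and its annotation sidecar
#'
#' @param expr_path CSV with a leading `gene` column.
#' @param samples_path CSV with columns `sample_id`, `population` (and
#'   optionally `replicate`, `genotype`, `stage`).
#' @return A list with `expr` (matrix) and `samples` (data.table).
#' @export
read_expression <- function(expr_path, samples_path) {
  m <- fread(expr_path)
  if (!"gene" %in% names(m))
    stop_fmt("format error: expression matrix needs a 'gene' column")
  genes <- m$gene
  if (anyDuplicated(genes))
    stop_fmt("validation error: duplicate gene ids in expression matrix")
  expr <- as.matrix(m[, !"gene"])
  rownames(expr) <- genes
  samples <- fread(samples_path, colClasses = list(character = "sample_id"))
  missing <- setdiff(colnames(expr), samples$sample_id)
  if (length(missing))
    stop_fmt("validation error: unannotated sample(s): %s",
             paste(missing, collapse = ", "))
  list(expr = expr, samples = samples)
}
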