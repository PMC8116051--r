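## Command-line orchestration: subcommands, JSON configuration, manifests.

SUBCOMMANDS <- c("simulate-tracks", "detect", "align", "motility",
                 "export-timepoints", "simulate-expression", "signature",
                 "ion-filter", "cluster")

#' Read a pipeline configuration file
#'
#' Configuration is a JSON object whose top-level keys name the stage blocks
#' (`acquisition`, `detection`, `simulate`, `simulate_expression`,
#' `alignment`, `signature`, `ion_filter`, `cluster`) plus `inputs`,
#' `out_dir`, and `seed`. Any block may be omitted; defaults apply.
#'
#' @param path Path to a JSON file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_fmt("no such config file: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

config_acq <- function(config) {
  a <- config$acquisition %||% list()
  acquisition_params(frame_interval_s = a$frame_interval_s %||% 10,
                     speed_smoothing_window = a$speed_smoothing_window %||% 2L)
}

config_det <- function(config) {
  d <- config$detection %||% list()
  detection_params(background = d$background,
                   delta_high = d$delta_high %||% 0.2,
                   delta_low = d$delta_low %||% 0.1,
                   min_consecutive = d$min_consecutive %||% 2L,
                   quiescence_gap_s = d$quiescence_gap_s %||% 240,
                   smooth_window = d$smooth_window %||% 1L)
}

## atomically write a set of tables/objects: build in a temp dir inside
## out_dir, then rename into place; on failure nothing is left behind
write_outputs <- function(out_dir, writers) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile("stage", tmpdir = out_dir)
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  paths <- character(0)
  for (name in names(writers)) {
    p <- file.path(tmp, name)
    writers[[name]](p)
    paths[name] <- p
  }
  final <- file.path(out_dir, names(paths))
  ok <- file.rename(paths, final)
  if (!all(ok)) stop_fmt("failed to move outputs into %s", out_dir)
  final
}

write_manifest <- function(out_dir, subcommand, config, seed, inputs,
                           outputs) {
  manifest <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("thymotrack")),
    seed = seed,
    config = config,
    input_md5 = as.list(md5sum(inputs[file.exists(inputs)])),
    output_md5 = as.list(md5sum(outputs)))
  path <- file.path(out_dir, paste0("manifest_", subcommand, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

#' Run one pipeline stage
#'
#' Executes the named subcommand against a configuration list (see
#' [read_pipeline_config()]), writes its artifacts atomically under
#' `config$out_dir`, and writes a run manifest (parameters, seed, input and
#' output digests, package version) alongside them. With the same
#' configuration and seed, outputs are byte-identical across runs.
#'
#' Subcommands and their artifacts:
#' \describe{
#'   \item{simulate-tracks}{`tracks.csv`, `truth_events.csv`}
#'   \item{detect}{`events.csv`, `summary.csv` (per-condition kinetics)}
#'   \item{align}{`aligned_profile.csv`}
#'   \item{motility}{`pause_records.csv`}
#'   \item{export-timepoints}{`timepoints.csv`}
#'   \item{simulate-expression}{`expression.csv`, `samples.csv`,
#'     `planted_genes.txt`}
#'   \item{signature}{`signature.csv`}
#'   \item{ion-filter}{`ion_channels.txt`}
#'   \item{cluster}{`scaled_matrix.csv`, `clusters.csv`}
#' }
#'
#' @param name Subcommand name; one of `simulate-tracks`, `detect`,
#'   `align`, `motility`, `export-timepoints`, `simulate-expression`,
#'   `signature`, `ion-filter`, `cluster`.
#' @param config Configuration list (or path to a JSON config file).
#' @return Invisibly, a character vector of written artifact paths
#'   (manifest last).
#' @export
run_subcommand <- function(name, config) {
  name <- match.arg(name, SUBCOMMANDS)
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  out_dir <- config$out_dir %||% "."
  seed <- config$seed
  acq <- config_acq(config)
  inputs <- as.character(unlist(config$inputs %||% list()))
  load_tracks <- function() {
    if (is.null(config$inputs$tracks))
      stop_fmt("invalid config: inputs.tracks is required for '%s'", name)
    read_tracks(config$inputs$tracks, acq)
  }
  detect_all <- function(tracks) {
    det <- config_det(config)
    traces <- compute_ratio(tracks)
    if (is.null(det$background)) {
      det$background <- estimate_background(traces)
    }
    list(traces = traces,
         speeds = suppressWarnings(compute_speed(tracks, acq)),
         events = detect_events(traces, det), det = det)
  }
  outputs <- switch(
    name,
    "simulate-tracks" = {
      sim_cfg <- config$simulate %||% list()
      sim_cfg$seed <- sim_cfg$seed %||% seed
      p <- do.call(track_sim_params, sim_cfg)
      sim <- simulate_tracks(p)
      write_outputs(out_dir, list(
        "tracks.csv" = function(f) write_tracks(sim$tracks, f),
        "truth_events.csv" = function(f) fwrite(sim$truth$events, f)))
    },
    "detect" = {
      d <- detect_all(load_tracks())
      summ <- summarize_kinetics(d$traces, d$speeds, d$events, d$det)
      write_outputs(out_dir, list(
        "events.csv" = function(f) fwrite(event_table(d$events), f),
        "summary.csv" = function(f) fwrite(summ, f)))
    },
    "align" = {
      d <- detect_all(load_tracks())
      al <- config$alignment %||% list()
      prof <- align_events(d$traces, d$speeds, d$events,
                           window_pre_s = al$window_pre_s %||% 60,
                           window_post_s = al$window_post_s %||% 600,
                           align = al$align %||% "first",
                           speed_source = al$speed_source %||% "smooth")
      write_outputs(out_dir, list(
        "aligned_profile.csv" = function(f) fwrite(prof, f)))
    },
    "motility" = {
      d <- detect_all(load_tracks())
      pr <- suppressWarnings(pause_index(d$speeds, d$events))
      write_outputs(out_dir, list(
        "pause_records.csv" = function(f) fwrite(pr, f)))
    },
    "export-timepoints" = {
      tracks <- load_tracks()
      d <- detect_all(tracks)
      tp <- export_timepoint_table(tracks, d$traces, d$speeds, d$events)
      write_outputs(out_dir, list(
        "timepoints.csv" = function(f) fwrite(tp, f)))
    },
    "simulate-expression" = {
      se_cfg <- config$simulate_expression %||% list()
      se_cfg$seed <- se_cfg$seed %||% seed
      p <- do.call(expr_sim_params, se_cfg)
      sim <- simulate_expression(p)
      write_outputs(out_dir, list(
        "expression.csv" = function(f)
          fwrite(as.data.table(sim$expr, keep.rownames = "gene"), f),
        "samples.csv" = function(f) fwrite(sim$samples, f),
        "planted_genes.txt" = function(f) writeLines(sim$planted, f)))
    },
    "signature" = {
      ex <- read_expression(config$inputs$expression, config$inputs$samples)
      sc <- do.call(signature_criteria, config$signature %||% list())
      sig <- derive_preselection_signature(ex$expr, ex$samples, sc)
      write_outputs(out_dir, list(
        "signature.csv" = function(f) fwrite(sig, f)))
    },
    "ion-filter" = {
      de <- fread(config$inputs$de)
      candidates <- readLines(config$inputs$candidates)
      ip <- do.call(ion_filter_params, config$ion_filter %||% list())
      expr <- if (!is.null(config$inputs$expression)) {
        read_expression(config$inputs$expression, config$inputs$samples)$expr
      }
      genes <- filter_ion_channels(candidates, de, ip, expr = expr)
      write_outputs(out_dir, list(
        "ion_channels.txt" = function(f) writeLines(genes, f)))
    },
    "cluster" = {
      ex <- read_expression(config$inputs$expression, config$inputs$samples)
      k <- config$cluster$k %||% 4L
      res <- scale_and_cluster(ex$expr, ex$samples, k = k)
      write_outputs(out_dir, list(
        "scaled_matrix.csv" = function(f)
          fwrite(as.data.table(res$scaled, keep.rownames = "gene"), f),
        "clusters.csv" = function(f)
          fwrite(data.table(gene = names(res$clusters),
                            cluster = unname(res$clusters)), f)))
    })
  manifest <- write_manifest(out_dir, name, config, seed, inputs, outputs)
  invisible(c(outputs, manifest))
}

#' Command-line entry point
#'
#' Parses `argv` of the form
#' `<subcommand> --config <file> [--seed <int>] [--out-dir <dir>]
#' [--background <num>] [--log-level <level>]` and dispatches to
#' [run_subcommand()]. Flags override the corresponding config entries.
#' Intended to be called from an Rscript wrapper (see
#' `system.file("scripts", "thymotrack", package = "thymotrack")`);
#' errors propagate as R conditions so the wrapper can exit nonzero.
#'
#' @param argv Character vector of command-line arguments.
#' @return Invisibly, the written artifact paths.
#' @export
thymotrack_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv))
    stop_fmt("usage: thymotrack <subcommand> --config <file> [--seed N] [--out-dir D] [--background B]")
  name <- argv[1L]
  if (!name %in% SUBCOMMANDS)
    stop_fmt("unknown subcommand '%s'; expected one of: %s", name,
             paste(SUBCOMMANDS, collapse = ", "))
  opts <- list()
  i <- 2L
  while (i <= length(argv)) {
    key <- argv[i]
    if (!startsWith(key, "--") || i == length(argv))
      stop_fmt("malformed argument '%s'", key)
    opts[[substring(key, 3L)]] <- argv[i + 1L]
    i <- i + 2L
  }
  config <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
            else list()
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  if (!is.null(opts$`out-dir`)) config$out_dir <- opts$`out-dir`
  if (!is.null(opts$background)) {
    config$detection <- config$detection %||% list()
    config$detection$background <- as.numeric(opts$background)
  }
  level <- opts$`log-level` %||% "info"
  if (!identical(level, "quiet"))
    message(sprintf("[%s] thymotrack %s -> %s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), name,
                    config$out_dir %||% "."))
  run_subcommand(name, config)
}
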