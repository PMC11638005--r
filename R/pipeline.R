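# End-to-end runs, configuration, fixture generation and CSV/JSON I/O.

#' Read and write trace tables
#'
#' Traces are exchanged as plain CSV with columns `track_id`, `frame`
#' (0-based) and `intensity_pe`, optionally `acquisition`. Schema
#' violations name the offending column.
#'
#' @param path CSV path.
#' @param tab Track table (as from [as_track_table] semantics).
#' @return `read_traces_csv()` returns the validated data frame;
#'   `write_traces_csv()` returns `path` invisibly.
#' @export
read_traces_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("track_id", "frame", "intensity_pe")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0)
    stop("trace CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cl in c("frame", "intensity_pe"))
    if (!is.numeric(tab[[cl]]))
      stop("trace CSV column '", cl, "' must be numeric")
  tab
}

#' @rdname read_traces_csv
#' @export
write_traces_csv <- function(tab, path) {
  if ("intensity" %in% names(tab) && !"intensity_pe" %in% names(tab))
    names(tab)[names(tab) == "intensity"] <- "intensity_pe"
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

population_to_table <- function(pop, acquisition = 1L) {
  tabs <- lapply(seq_along(pop$traces), function(i) {
    tr <- pop$traces[[i]]
    data.frame(acquisition = acquisition, track_id = i,
               frame = seq_along(tr) - 1L, intensity = tr)
  })
  do.call(rbind, tabs)
}

#' Run configuration for an end-to-end analysis
#'
#' Validates a configuration list (or YAML/JSON file) for
#' [run_end_to_end()]. Unknown keys are rejected so typos fail loudly; the
#' object round-trips losslessly through YAML.
#'
#' @param config Named list, or path to a YAML/JSON file containing one.
#' @return Validated config list of class `slim_run_config`.
#' @export
slim_run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    mode = "simulate", traces_csv = NULL, out_dir = NULL, seed = 1L,
    n_acquisitions = 1L,
    n_complexes = 347L, unit_stoichiometry = 5L,
    multiple_weights = c(0.6, 0.25, 0.1, 0.05),
    brightness_pe = 56, bleach_prob = 0.004, detection_fraction = 1.0,
    noise_sd_pe = 9, n_frames = 900L,
    kernel_width = 0.7, prominence_frac = 0.05, start_frame_limit = 4L,
    min_track_length = 4L, n_boot = 1000L
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$mode %in% c("simulate", "traces"))
    stop("config field 'mode' must be \"simulate\" or \"traces\"")
  if (cfg$mode == "traces" && is.null(cfg$traces_csv))
    stop("config field 'traces_csv' is required when mode = \"traces\"")
  structure(cfg, class = "slim_run_config")
}

#' Run the whole counting analysis end to end
#'
#' Either simulates a population under the configured ground truth
#' (`mode = "simulate"`, possibly over several acquisitions) or loads a
#' trace CSV (`mode = "traces"`), then runs [run_counting_pipeline()]. The
#' run is deterministic under the configured seed; when `out_dir` is set, a
#' machine-readable `report.json` and a per-track `stoichiometries.csv` are
#' written there.
#'
#' @param config A [slim_run_config()], a config list, or a YAML/JSON path.
#' @return A `run_report` list: `config`, `package_version`, `report` (the
#'   `counting_report`), `summary` (flat named results), `timestamp`.
#' @export
run_end_to_end <- function(config = list()) {
  cfg <- if (inherits(config, "slim_run_config")) config
         else slim_run_config(config)
  set.seed(cfg$seed)
  if (cfg$mode == "simulate") {
    params <- simulation_params(
      unit_stoichiometry = cfg$unit_stoichiometry,
      multiple_weights = cfg$multiple_weights,
      brightness_pe = cfg$brightness_pe, bleach_prob = cfg$bleach_prob,
      detection_fraction = cfg$detection_fraction,
      noise_sd_pe = cfg$noise_sd_pe,
      n_complexes = max(1L, round(cfg$n_complexes / cfg$n_acquisitions)))
    acq_cfg <- acquisition_config(n_frames = cfg$n_frames)
    tab <- do.call(rbind, lapply(seq_len(cfg$n_acquisitions), function(a)
      population_to_table(simulate_population(params, acq_cfg),
                          acquisition = a)))
  } else {
    tab <- read_traces_csv(cfg$traces_csv)
  }
  report <- run_counting_pipeline(
    tab, kernel_width = cfg$kernel_width,
    prominence_frac = cfg$prominence_frac,
    start_frame_limit = cfg$start_frame_limit,
    min_track_length = cfg$min_track_length,
    n_frames = if (cfg$mode == "simulate") cfg$n_frames else NULL,
    n_boot = cfg$n_boot)
  summary <- list(
    brightness_pe = report$calibration$brightness_pe,
    uncertainty_pe = report$calibration$uncertainty_pe,
    n_tracks = report$n_tracks,
    peaks = report$peaks,
    periodicity_mode = if (is.null(report$periodicity)) NULL
                       else report$periodicity$mode,
    ci95 = if (is.null(report$periodicity)) NULL
           else unname(report$periodicity$ci95),
    n_intervals = report$n_intervals)
  out <- list(config = unclass(cfg),
              package_version = as.character(packageVersion("slimcount")),
              report = report, summary = summary,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(out) <- "run_report"
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    json <- c(list(config = unclass(cfg)[!vapply(cfg, is.null, TRUE)],
                   package_version = out$package_version,
                   timestamp = out$timestamp),
              summary[!vapply(summary, is.null, TRUE)])
    jsonlite::write_json(json, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(report$stoichiometries,
              file.path(cfg$out_dir, "stoichiometries.csv"),
              row.names = FALSE)
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("slimcount end-to-end run (seed ", x$config$seed, ")\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Generate a self-contained fixture bundle
#'
#' Writes, under `out_dir`: a small photobleaching trace CSV with its
#' ground-truth sidecar, a tiny rendered TIFF stack with its true-centroid
#' table, a PAM pulse CSV, and an ECS trace CSV, each with a JSON sidecar
#' recording the injected truth. Byte-identical across runs for the same
#' seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed for the whole bundle.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  files <- c()

  # photobleaching traces (short record, faster bleaching to keep it small)
  params <- simulation_params(n_complexes = 12, multiple_weights = c(0.7, 0.3),
                              bleach_prob = 0.02)
  cfg <- acquisition_config(n_frames = 120)
  pop <- simulate_population(params, cfg)
  traces_path <- file.path(out_dir, "traces.csv")
  write_traces_csv(population_to_table(pop), traces_path)
  truth_path <- file.path(out_dir, "traces_truth.csv")
  write.csv(pop$truth, truth_path, row.names = FALSE)
  files <- c(files, traces = traces_path, traces_truth = truth_path)

  # tiny rendered stack
  stack_params <- simulation_params(n_complexes = 3, multiple_weights = 1,
                                    bleach_prob = 0.05, noise_sd_pe = 0)
  stack_cfg <- acquisition_config(n_frames = 30, image_shape = c(48L, 48L))
  stack_pop <- simulate_population(stack_params, stack_cfg)
  rendered <- render_image_stack(stack_pop, stack_cfg, background_pe = 5)
  tif_path <- file.path(out_dir, "stack.tif")
  write_stack_tiff(rendered$stack, tif_path, pe_per_count = 0.1)
  cent_path <- file.path(out_dir, "stack_centroids.csv")
  write.csv(rendered$centroids, cent_path, row.names = FALSE)
  files <- c(files, stack = tif_path, stack_centroids = cent_path)

  # PAM record with a qE-like dark relaxation
  times <- seq(0, 300, by = 20)
  phase <- ifelse(times <= 180, "light", "dark")
  qe <- 0.8
  npq_vals <- ifelse(times <= 180, 0.4 + qe * times / 180,
                     0.4 + qe * exp(-(times - 180) / 40))
  pam <- simulate_pam_trace(times, phase, npq_vals)
  pam_path <- file.path(out_dir, "pam.csv")
  write.csv(as.data.frame(pam), pam_path, row.names = FALSE)
  jsonlite::write_json(list(fm = 1.0, fo = 0.2, qe_amplitude = qe),
                       file.path(out_dir, "pam_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, pam = pam_path,
             pam_truth = file.path(out_dir, "pam_truth.json"))

  # ECS trace
  ecs <- simulate_ecs_trace(pmf_true = 1.0, tau_true = 0.1,
                            dpsi_frac = 0.3, dt = 0.002, ecs_st = 1.0)
  ecs_tab <- data.frame(time_s = ecs$time_s, a520 = ecs$a520,
                        a545 = ecs$a545,
                        light = as.integer(ecs$time_s < ecs$light_off_time_s))
  ecs_path <- file.path(out_dir, "ecs.csv")
  write.csv(ecs_tab, ecs_path, row.names = FALSE)
  jsonlite::write_json(
    list(pmf_true = 1.0, tau_true = 0.1, dpsi_frac = 0.3,
         light_off_time_s = ecs$light_off_time_s, ecs_st = 1.0),
    file.path(out_dir, "ecs_truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, ecs = ecs_path,
             ecs_truth = file.path(out_dir, "ecs_truth.json"))
  invisible(files)
}

#' Read an ECS trace CSV
#'
#' Expects columns `time_s`, `a520`, `a545` and `light` (1 while the
#' actinic light is on); the light-off time is the last lit sample.
#'
#' @param path CSV path.
#' @param ecs_st Optional normalization amplitude.
#' @return An `ecs_trace` list usable by [pmf()], [g_h()],
#'   [ecs_partition()].
#' @export
read_ecs_csv <- function(path, ecs_st = NULL) {
  tab <- read.csv(path)
  req <- c("time_s", "a520", "a545", "light")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0)
    stop("ECS CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  structure(
    list(time_s = tab$time_s, a520 = tab$a520, a545 = tab$a545,
         light_off_time_s = max(tab$time_s[tab$light == 1]),
         ecs_st = ecs_st),
    class = "ecs_trace"
  )
}
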