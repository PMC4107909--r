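# End-to-end pipeline: simulate (or load) -> register -> detect ->
# merge -> trace -> call -> profile, with a serializable configuration
# and a run directory of CSV/JSON outputs.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one serializable object.
#' `load_pipeline_config(save_pipeline_config(c))` round-trips.
#'
#' @param simulate logical; when `TRUE` the run generates its inputs with
#'   [generate_slice_movie()] instead of reading files.
#' @param sim a [sim_config()] (used when `simulate = TRUE`).
#' @param stimuli data.frame (`label`, `concentration_M`) of the delivery
#'   panel for simulated runs.
#' @param epoch_s,gap_s schedule layout for simulated runs, seconds.
#' @param movie_path,schedule_path,colabel_path input files for real runs
#'   (multi-page TIFF; schedule JSON; optional co-label TIFF).
#' @param detection a [detection_params()].
#' @param response_window_s peak-search / baseline-mask window, seconds.
#' @param response_threshold responder threshold on dF/F (default 0.30).
#' @param seed integer seed for the whole run.
#' @param out_dir run directory to create.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE,
                            sim = sim_config(),
                            stimuli = data.frame(
                              label = c("SE", "EU", "NEU", "KCl"),
                              concentration_M = c(1e-7, NA, NA, NA)),
                            epoch_s = 10, gap_s = 120,
                            movie_path = NULL, schedule_path = NULL,
                            colabel_path = NULL,
                            detection = detection_params(),
                            response_window_s = 60,
                            response_threshold = 0.30,
                            seed = 1L,
                            out_dir = "vnoca_run") {
  structure(list(simulate = simulate, sim = sim, stimuli = stimuli,
                 epoch_s = epoch_s, gap_s = gap_s,
                 movie_path = movie_path, schedule_path = schedule_path,
                 colabel_path = colabel_path, detection = detection,
                 response_window_s = response_window_s,
                 response_threshold = response_threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `load_pipeline_config` returns a [pipeline_config()].
#' @export
save_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj$sim <- unclass(obj$sim)
  obj$detection <- unclass(obj$detection)
  # named vectors must serialize as JSON objects, not unboxed scalars
  if (!is.null(obj$sim$tuning_classes))
    obj$sim$tuning_classes <- lapply(obj$sim$tuning_classes, function(cl) {
      cl$response_prob <- as.list(cl$response_prob)
      cl$amplitude <- as.list(cl$amplitude)
      cl
    })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_pipeline_config
#' @export
load_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- obj$sim
  # tuning classes hold named vectors; rebuild them from the raw tree
  tc <- jsonlite::read_json(path, simplifyVector = FALSE)$sim$tuning_classes
  if (!is.null(tc)) {
    tc <- lapply(tc, function(cl)
      list(label = cl$label, fraction = cl$fraction,
           response_prob = unlist(cl$response_prob),
           amplitude = unlist(cl$amplitude)))
  }
  cfg <- pipeline_config(
    simulate = obj$simulate,
    sim = do.call(sim_config, c(list(
      image_shape = sim$image_shape, n_frames = sim$n_frames,
      frame_interval = sim$frame_interval, n_cells = sim$n_cells,
      cell_radius_range = sim$cell_radius_range,
      baseline_intensity_range = sim$baseline_intensity_range,
      bleach_tau = sim$bleach_tau, noise_sigma = sim$noise_sigma,
      transient_amplitude = sim$transient_amplitude,
      transient_rise_tau = sim$transient_rise_tau,
      transient_decay_tau = sim$transient_decay_tau,
      drift_per_frame = sim$drift_per_frame,
      se_tuned_fraction = sim$se_tuned_fraction,
      colabel_fraction = sim$colabel_fraction,
      hill_ec50 = sim$hill_ec50, hill_coefficient = sim$hill_coefficient,
      min_separation_px = sim$min_separation_px,
      depolarization_label = sim$depolarization_label,
      seed = sim$seed),
      list(tuning_classes = tc))),
    stimuli = as.data.frame(obj$stimuli),
    epoch_s = obj$epoch_s, gap_s = obj$gap_s,
    movie_path = obj$movie_path, schedule_path = obj$schedule_path,
    colabel_path = obj$colabel_path,
    detection = do.call(detection_params, as.list(obj$detection)),
    response_window_s = obj$response_window_s,
    response_threshold = obj$response_threshold,
    seed = obj$seed, out_dir = obj$out_dir)
  cfg
}

#' Analyze one registered-or-raw movie into a response matrix
#'
#' The single-slice core of the pipeline: register to frame 1, detect
#' local ROIs per scheduled event, filter candidates, merge to global
#' ROIs, and call every (ROI, event) response.
#'
#' @param movie a [ca_movie()].
#' @param schedule a [stim_schedule()].
#' @param detection a [detection_params()].
#' @param response_window_s,response_threshold see [call_response()].
#' @param slice_id identifier for pooled analyses.
#' @return list: `matrix` (a `response_matrix`), `rois` (global ROIs),
#'   `shifts` (registration shifts), `n_local` (per-event candidate
#'   counts after filtering).
#' @export
analyze_movie <- function(movie, schedule,
                          detection = detection_params(),
                          response_window_s = 60,
                          response_threshold = 0.30,
                          slice_id = "slice1") {
  reg <- register_frames(movie)
  local_sets <- vector("list", nrow(schedule))
  for (e in seq_len(nrow(schedule))) {
    cand <- detect_local_rois(reg$movie, schedule_event(schedule, e),
                              detection)
    local_sets[[e]] <- filter_candidates(cand, detection)
  }
  rois <- merge_to_global(local_sets, detection,
                          image_shape = dim(movie$frames)[1:2])
  mat <- build_response_matrix(reg$movie, rois, schedule,
                               response_window_s, response_threshold,
                               slice_id = slice_id)
  list(matrix = mat, rois = rois, shifts = reg$shifts,
       n_local = vapply(local_sets, length, integer(1)))
}

#' Run the full pipeline into a run directory
#'
#' Executes simulate/load -> register -> detect -> merge -> trace ->
#' call -> profile and writes: `rois.json`, `rois.csv`, `calls.csv`,
#' `shifts.csv`, `percent_responding.csv`, `schedule.json`,
#' `config.json` (the resolved configuration) and `log.txt` (versions,
#' seed, stage timings).
#'
#' @param config a [pipeline_config()].
#' @return The run directory path, invisibly; the full results list as
#'   attribute `results`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat(sprintf("vnoca %s | R %s | seed %d\n",
              as.character(utils::packageVersion("vnoca")),
              paste(R.version$major, R.version$minor, sep = "."),
              config$seed),
      file = logf)

  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    log_line("stage %-10s %.1fs", name, proc.time()[3] - t0)
    res
  }

  if (isTRUE(config$simulate)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    schedule <- stage("schedule",
      generate_stimulus_schedule(sim_cfg, config$stimuli,
                                 epoch_s = config$epoch_s,
                                 gap_s = config$gap_s))
    sim <- stage("simulate", generate_slice_movie(sim_cfg, schedule))
    movie <- sim$movie
    gt <- sim$ground_truth
  } else {
    if (is.null(config$movie_path) || !file.exists(config$movie_path))
      stop("movie file not found: ",
           config$movie_path %||% "<missing movie_path>")
    if (is.null(config$schedule_path) || !file.exists(config$schedule_path))
      stop("schedule file not found: ",
           config$schedule_path %||% "<missing schedule_path>")
    schedule <- read_schedule_json(config$schedule_path)
    movie <- stage("load", read_movie_tiff(config$movie_path,
                                           attr(schedule, "frame_interval")))
    gt <- NULL
  }

  ana <- stage("analyze",
    analyze_movie(movie, schedule, config$detection,
                  config$response_window_s, config$response_threshold,
                  slice_id = "slice1"))

  pr <- do.call(rbind, lapply(unique(schedule$label), function(s) {
    p <- percent_responding(ana$matrix, s)
    data.frame(stimulus = s, percent = p$percent,
               n_responding = p$n_responding,
               n_denominator = p$n_denominator)
  }))

  out <- config$out_dir
  write_rois_json(ana$rois, file.path(out, "rois.json"))
  write_rois_csv(ana$rois, file.path(out, "rois.csv"))
  write_calls_csv(ana$matrix, file.path(out, "calls.csv"))
  write_shifts_csv(ana$shifts, file.path(out, "shifts.csv"))
  utils::write.csv(pr, file.path(out, "percent_responding.csv"),
                   row.names = FALSE)
  write_schedule_json(schedule, file.path(out, "schedule.json"))
  save_pipeline_config(config, file.path(out, "config.json"))
  log_line("rois %d | calls %d", length(ana$rois), nrow(ana$matrix))

  res <- list(matrix = ana$matrix, rois = ana$rois, shifts = ana$shifts,
              percent_responding = pr, schedule = schedule,
              ground_truth = gt)
  invisible(structure(out, results = res))
}
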