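#' Build a pipeline run configuration
#'
#' One configuration drives the whole two-phase analysis (calibration
#' then validation) so a run is reproducible from the config and seed
#' alone. See [run_pipeline()].
#'
#' @param seed Integer RNG seed for the entire run.
#' @param out_dir Directory receiving all artifacts.
#' @param calibration_participants Calibration cohort size.
#' @param validation_participants Validation cohort size.
#' @param calibration_distance Calibration course length, m (single
#'   distance).
#' @param validation_distances Validation course lengths, m.
#' @param platforms Device platform labels.
#' @param trials_per_cell Trials per design cell.
#' @param grids Named list of per-speed [settings_grid()]; defaults to
#'   [default_grid()] for each speed.
#' @param gait Optional `gait_params` template for the simulator.
#' @param write_traces Write every simulated trace to CSV (off by
#'   default: traces are regenerable from config + seed).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "shakestep-run",
                       calibration_participants = 5,
                       validation_participants = 52,
                       calibration_distance = 20,
                       validation_distances = c(6, 10, 20),
                       platforms = c("ios", "android"),
                       trials_per_cell = 3,
                       grids = list(slow = default_grid("slow"),
                                    normal = default_grid("normal")),
                       gait = NULL, write_traces = FALSE) {
  if (length(grids) == 0 || any(!vapply(grids, length, 0)))
    stop("`grids` must contain at least one non-empty settings grid per speed")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 calibration_participants = calibration_participants,
                 validation_participants = validation_participants,
                 calibration_distance = calibration_distance,
                 validation_distances = validation_distances,
                 platforms = platforms, trials_per_cell = trials_per_cell,
                 grids = grids, gait = gait, write_traces = write_traces),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  plain <- rapply(unclass(config), unclass, how = "replace")
  plain$out_dir <- NULL   # hash the scientific configuration, not the paths
  saveRDS(plain, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

stage <- function(name, expr, verbose = TRUE) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full two-phase pipeline
#'
#' Sequences the whole analysis: simulate the calibration cohort; count
#' its trials under every grid candidate; calibrate (per-speed error
#' summaries, NB-GEE setting comparison, setting selection); simulate
#' the validation cohort; count with the selected settings plus the
#' fixed baseline; and run the per-cell validation models. All artifacts
#' are written under `config$out_dir`, stamped with the config hash and
#' seed; any stage failure aborts with the stage name while artifacts
#' already written are preserved.
#'
#' @param config A [run_config()] (or path to a JSON file of its fields).
#' @param verbose Log per-stage progress messages.
#' @return Invisible list: `trials_calibration`, `records_calibration`,
#'   `calibration`, `trials_validation`, `records_validation`, `report`,
#'   `summaries`, `meta`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = config$seed, config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("shakestep")))
  out <- function(f) file.path(config$out_dir, f)

  calib <- stage("simulate-calibration", {
    simulate_cohort(cohort_spec(
      n_participants = config$calibration_participants,
      distances = config$calibration_distance,
      speed_categories = names(config$grids),
      platforms = config$platforms,
      trials_per_cell = config$trials_per_cell,
      gait = config$gait, seed = config$seed))
  }, verbose)
  write_trials(calib$trials, out("trials_calibration.csv"))
  if (config$write_traces) {
    dir.create(out("traces_calibration"), showWarnings = FALSE)
    for (tid in names(calib$traces))
      write_trace(calib$traces[[tid]],
                  file.path(out("traces_calibration"), paste0(tid, ".csv")))
  }

  grid_records <- stage("detect-grid", {
    do.call(rbind, lapply(names(config$grids), function(sp)
      apply_settings_grid(
        calib$traces,
        calib$trials[calib$trials$speed_category == sp, , drop = FALSE],
        config$grids[[sp]])))
  }, verbose)
  write_records(grid_records, out("records_calibration.csv"))
  if (verbose) message("  calibration records: ", nrow(grid_records))

  calibration <- stage("calibrate", {
    run_calibration(grid_records, calib$trials, config$grids)
  }, verbose)
  calib_json <- list(
    meta = meta,
    selected = calibration$selected,
    per_speed = lapply(calibration$per_speed, function(x)
      list(errors = x$errors, irr = x$irr, referent_label = x$referent_label)))
  jsonlite::write_json(calib_json, out("calibration.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  valid <- stage("simulate-validation", {
    simulate_cohort(cohort_spec(
      n_participants = config$validation_participants,
      distances = config$validation_distances,
      speed_categories = names(config$grids),
      platforms = config$platforms,
      trials_per_cell = config$trials_per_cell,
      gait = config$gait, seed = config$seed + 1L))
  }, verbose)
  write_trials(valid$trials, out("trials_validation.csv"))

  records <- stage("detect-validation", {
    count_trials(valid$traces, valid$trials, calibration$selected_settings)
  }, verbose)
  write_records(records, out("records_validation.csv"))
  if (verbose) message("  validation records: ", nrow(records))

  report <- stage("validate", {
    run_validation(records, valid$trials)
  }, verbose)
  summaries <- summarize_cells(records, valid$trials)
  utils::write.csv(report, out("validation_report.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(meta = meta, cells = report, summaries = summaries),
    out("validation_report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  writeLines(validation_markdown(report), out("validation_report.md"))
  jsonlite::write_json(meta, out("run_meta.json"), auto_unbox = TRUE)

  invisible(list(trials_calibration = calib$trials,
                 records_calibration = grid_records,
                 calibration = calibration,
                 trials_validation = valid$trials,
                 records_validation = records,
                 report = report, summaries = summaries, meta = meta))
}

#' Read a pipeline configuration from JSON
#'
#' Accepts the fields of [run_config()]; `grids` uses the schema of
#' [read_grid_json()].
#'
#' @param path JSON file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path)
  grids <- if (!is.null(js$grids)) {
    lapply(js$grids, function(g) {
      if (!is.null(g$candidates))
        settings_grid(lapply(g$candidates, function(s)
          detector_settings(s$sensitivity, s$refresh_ms)))
      else settings_grid(unlist(g$sensitivities), unlist(g$refresh_times))
    })
  } else list(slow = default_grid("slow"), normal = default_grid("normal"))
  run_config(
    seed = js$seed %||% 1L,
    out_dir = js$out_dir %||% "shakestep-run",
    calibration_participants = js$calibration_participants %||% 5,
    validation_participants = js$validation_participants %||% 52,
    calibration_distance = js$calibration_distance %||% 20,
    validation_distances = unlist(js$validation_distances) %||% c(6, 10, 20),
    platforms = unlist(js$platforms) %||% c("ios", "android"),
    trials_per_cell = js$trials_per_cell %||% 3,
    grids = grids,
    write_traces = isTRUE(js$write_traces))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
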