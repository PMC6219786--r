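# CSV schema version comment lines: every artifact starts with one so
# readers can detect format drift.
TRACE_SCHEMA <- "# shakestep-trace v1"
TRIALS_SCHEMA <- "# shakestep-trials v1"
RECORDS_SCHEMA <- "# shakestep-records v1"

stop_io <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "shakestep_io_error")))
}

#' Write an accelerometer trace to CSV
#'
#' Plain CSV with a schema-version comment line and header
#' `t,ax,ay,az` (seconds, m/s^2). Round-trips through [read_trace()]
#' losslessly to well below 1e-9.
#'
#' @param trace An `accel_trace` or compatible data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(TRACE_SCHEMA, con)
  writeLines("t,ax,ay,az", con)
  writeLines(paste(format(trace$t, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   format(trace$ax, digits = 17, trim = TRUE),
                   format(trace$ay, digits = 17, trim = TRUE),
                   format(trace$az, digits = 17, trim = TRUE), sep = ","),
             con)
  invisible(path)
}

#' Read an accelerometer trace from CSV
#'
#' Validates structure as it parses: the header must be `t,ax,ay,az`,
#' every row must be four numbers, and timestamps must be strictly
#' increasing. Malformed rows and ordering violations are reported with
#' their file line numbers. An empty file raises a condition of class
#' `shakestep_empty_file`, distinct from the `shakestep_parse_error`
#' raised for malformed content.
#'
#' @param path CSV file path.
#' @param trial_id,device Optional metadata attached to the result.
#' @return An `accel_trace` data frame.
#' @export
read_trace <- function(path, trial_id = NULL, device = NULL) {
  if (!file.exists(path)) stop_io(paste0("no such file: ", path),
                                  "shakestep_missing_file")
  lines <- readLines(path, warn = FALSE)
  body_ix <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(body_ix) == 0)
    stop_io(paste0("empty trace file: ", path), "shakestep_empty_file")
  header <- gsub("\\s", "", lines[body_ix[1]])
  if (header != "t,ax,ay,az")
    stop_io(paste0(path, ": line ", body_ix[1],
                   ": expected header `t,ax,ay,az`, got `", header, "`"),
            "shakestep_parse_error")
  data_ix <- body_ix[-1]
  if (length(data_ix) == 0)
    stop_io(paste0(path, ": header but no data rows"), "shakestep_empty_file")
  parts <- strsplit(lines[data_ix], ",", fixed = TRUE)
  bad_shape <- lengths(parts) != 4L
  vals <- suppressWarnings(
    lapply(1:4, function(j) as.numeric(vapply(parts, function(p)
      if (length(p) >= j) p[j] else NA_character_, ""))))
  bad <- bad_shape | Reduce(`|`, lapply(vals, is.na))
  if (any(bad))
    stop_io(paste0(path, ": malformed row(s) at line(s) ",
                   paste(utils::head(data_ix[bad], 10), collapse = ", ")),
            "shakestep_parse_error")
  t <- vals[[1]]
  nonmono <- which(diff(t) <= 0)
  if (length(nonmono))
    stop_io(paste0(path, ": timestamps not strictly increasing; first ",
                   "offending line ", data_ix[nonmono[1] + 1L]),
            "shakestep_parse_error")
  trace <- data.frame(t = t, ax = vals[[2]], ay = vals[[3]], az = vals[[4]])
  attr(trace, "trial_id") <- trial_id
  attr(trace, "device") <- device
  class(trace) <- c("accel_trace", "data.frame")
  trace
}

write_table_schema <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(schema, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_schema <- function(path, required_cols) {
  if (!file.exists(path)) stop_io(paste0("no such file: ", path),
                                  "shakestep_missing_file")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop_io(paste0(path, ": missing column(s): ",
                   paste(missing, collapse = ", ")), "shakestep_parse_error")
  df
}

#' Write / read a trial table
#'
#' CSV with columns `trial_id, participant_id, platform, distance_m,
#' speed_category, realized_speed_mps, trial_index, observed_steps` and a
#' schema-version comment line.
#'
#' @param trials Trial-metadata data frame.
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns the data frame.
#' @export
write_trials <- function(trials, path)
  write_table_schema(trials, path, TRIALS_SCHEMA)

#' @rdname write_trials
#' @export
read_trials <- function(path)
  read_table_schema(path, c("trial_id", "participant_id", "platform",
                            "distance_m", "speed_category",
                            "realized_speed_mps", "trial_index",
                            "observed_steps"))

#' Write / read a step-count records table
#'
#' CSV with columns `trial_id, method, settings_label, counted_steps`.
#'
#' @param records Records data frame.
#' @param path File path.
#' @return `write_records()` returns `path` invisibly; `read_records()`
#'   returns the data frame.
#' @export
write_records <- function(records, path)
  write_table_schema(records, path, RECORDS_SCHEMA)

#' @rdname write_records
#' @export
read_records <- function(path)
  read_table_schema(path, c("trial_id", "method", "settings_label",
                            "counted_steps"))

#' Read per-speed detector settings from JSON
#'
#' Schema: `{"slow": {"sensitivity": 1.5, "refresh_ms": 500},
#' "normal": {"sensitivity": 2.5, "refresh_ms": 450}}`.
#'
#' @param path JSON file path.
#' @param detector_rate_hz Internal detector rate applied to all entries.
#' @return Named list of [detector_settings()].
#' @export
read_settings_json <- function(path, detector_rate_hz = 10) {
  js <- jsonlite::read_json(path)
  lapply(js, function(s)
    detector_settings(s$sensitivity, s$refresh_ms,
                      detector_rate_hz = detector_rate_hz))
}

#' Read per-speed settings grids from JSON
#'
#' Schema: `{"slow": {"sensitivities": [1,1.5,2],
#' "refresh_times": [400,450,500]}, "normal": {...}}`; alternatively a
#' per-speed list of explicit `{"sensitivity":..., "refresh_ms":...}`
#' candidates under a `"candidates"` key.
#'
#' @param path JSON file path.
#' @param detector_rate_hz Internal detector rate.
#' @return Named list of [settings_grid()] per speed category.
#' @export
read_grid_json <- function(path, detector_rate_hz = 10) {
  js <- jsonlite::read_json(path)
  lapply(js, function(g) {
    if (!is.null(g$candidates)) {
      settings_grid(lapply(g$candidates, function(s)
        detector_settings(s$sensitivity, s$refresh_ms,
                          detector_rate_hz = detector_rate_hz)))
    } else {
      settings_grid(unlist(g$sensitivities), unlist(g$refresh_times),
                    detector_rate_hz = detector_rate_hz)
    }
  })
}
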