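# Resample a trace's axes to the detector rate by linear interpolation.
# Returns list(t, ax, ay, az) on a regular grid spanning the trace.
resample_trace <- function(trace, rate_hz) {
  t <- trace$t
  grid <- seq(t[1], t[length(t)], by = 1 / rate_hz)
  list(t = grid,
       ax = approx(t, trace$ax, xout = grid)$y,
       ay = approx(t, trace$ay, xout = grid)$y,
       az = approx(t, trace$az, xout = grid)$y)
}

validate_trace <- function(trace) {
  if (is.null(trace) || !all(c("t", "ax", "ay", "az") %in% names(trace)))
    stop("a trace must have columns t, ax, ay, az")
  n <- length(trace$t)
  if (n >= 2 && any(diff(trace$t) <= 0))
    stop("trace timestamps must be strictly increasing")
  n
}

#' Count steps with the shake-service delta-threshold detector
#'
#' The shake-service event rule: the trace is linearly resampled to the
#' detector's internal rate; for every consecutive resampled pair the
#' per-axis absolute deltas are computed; an event is registered at a
#' sample when the maximum delta across the three axes exceeds
#' `sensitivity` *and* at least `refresh_ms` milliseconds have elapsed
#' since the previous event (crossings inside the refractory window are
#' discarded, not deferred). Simultaneous crossings on several axes are a
#' single event. The detector sees only differences, so it is invariant
#' to any constant offset per axis (including gravity).
#'
#' @param trace An `accel_trace` (or any data frame with columns `t`,
#'   `ax`, `ay`, `az`; seconds and m/s^2).
#' @param settings A [detector_settings()] object.
#' @return A list: `count` (integer number of events) and `event_times`
#'   (strictly increasing, consecutive gaps >= `refresh_ms`/1000 s).
#' @examples
#' st <- simulate_trial(gait_params(speed = 1.3, seed = 2), distance = 10)
#' detect_steps(st$trace, detector_settings(2.5, 450))$count
#' @export
detect_steps <- function(trace, settings) {
  if (!inherits(settings, "detector_settings"))
    stop("`settings` must be a detector_settings object")
  n <- validate_trace(trace)
  if (n < 2) {
    warning("trace has fewer than 2 samples; returning 0 events")
    return(list(count = 0L, event_times = numeric(0)))
  }
  rs <- resample_trace(trace, settings$detector_rate_hz)
  if (length(rs$t) < 2) {
    warning("trace shorter than one detector sample interval; 0 events")
    return(list(count = 0L, event_times = numeric(0)))
  }
  delta <- pmax(abs(diff(rs$ax)), abs(diff(rs$ay)), abs(diff(rs$az)))
  cross <- which(delta > settings$sensitivity)
  refractory <- settings$refresh_ms / 1000
  events <- numeric(0)
  last <- -Inf
  for (i in cross) {
    ti <- rs$t[i + 1L]
    if (ti - last >= refractory) {
      events <- c(events, ti)
      last <- ti
    }
  }
  list(count = length(events), event_times = events)
}

# frozen constants of the native-pedometer stand-in: deliberately not
# arguments, mirroring non-tunable embedded step software
NATIVE_RATE_HZ <- 60
NATIVE_BAND_HZ <- c(0.5, 3)
NATIVE_PEAK_MIN <- 2.2      # m/s^2, fixed peak threshold
NATIVE_PEAK_SEP_S <- 0.3    # minimum peak separation

#' Fixed-parameter baseline step counter
#'
#' A non-tunable comparator standing in for the phone's built-in
#' pedometer. The acceleration magnitude is band-pass filtered to the
#' walking band (0.5-3 Hz, zero-phase Butterworth) and steps are counted
#' as peaks above a fixed 2.2 m/s^2 threshold separated by at least
#' 0.3 s. All parameters are frozen constants: the point of the baseline
#' is "one size fits all" behaviour, which counts accurately when the
#' oscillation amplitude clears the fixed threshold (typical at normal
#' walking speed) and undercounts when it does not (typical at slow
#' speed).
#'
#' @param trace An `accel_trace` (columns `t`, `ax`, `ay`, `az`).
#' @return Integer step count.
#' @export
count_native_baseline <- function(trace) {
  n <- validate_trace(trace)
  if (n < 2) {
    warning("trace has fewer than 2 samples; returning 0 steps")
    return(0L)
  }
  rs <- resample_trace(trace, NATIVE_RATE_HZ)
  mag <- sqrt(rs$ax^2 + rs$ay^2 + rs$az^2)
  if (length(mag) < 24) return(0L)  # too short to filter meaningfully
  bf <- signal::butter(2, NATIVE_BAND_HZ / (NATIVE_RATE_HZ / 2), type = "pass")
  filt <- signal::filtfilt(bf, mag - mean(mag))
  pk <- pracma::findpeaks(filt, minpeakheight = NATIVE_PEAK_MIN,
                          minpeakdistance = ceiling(NATIVE_PEAK_SEP_S *
                                                      NATIVE_RATE_HZ))
  if (is.null(pk)) 0L else nrow(pk)
}

#' Count every trial with shake, baseline and observed methods
#'
#' Produces the long-format step-count records behind all downstream
#' statistics: for each trial, one `shake` record (counted with the
#' detector settings assigned to that trial's speed category), one
#' `native_baseline` record, and one `observed` record carrying the
#' ground-truth step count.
#'
#' @param traces Named list of traces keyed by trial_id.
#' @param trials Trial-metadata data frame (as from [simulate_cohort()]).
#' @param settings_per_speed Named list mapping each speed category
#'   present in `trials` to a [detector_settings()] object, e.g.
#'   [default_settings()].
#' @return Data frame with columns `trial_id`, `method`,
#'   `settings_label` (NA except for shake rows) and `counted_steps`.
#' @export
count_trials <- function(traces, trials, settings_per_speed) {
  missing_tr <- setdiff(trials$trial_id, names(traces))
  if (length(missing_tr))
    stop("no trace for trial(s): ", paste(missing_tr, collapse = ", "))
  cats <- unique(trials$speed_category)
  missing_set <- setdiff(cats, names(settings_per_speed))
  if (length(missing_set))
    stop("no detector settings for speed categor",
         if (length(missing_set) > 1) "ies: " else "y: ",
         paste(missing_set, collapse = ", "))
  recs <- lapply(seq_len(nrow(trials)), function(i) {
    tid <- trials$trial_id[i]
    st <- settings_per_speed[[trials$speed_category[i]]]
    shake <- detect_steps(traces[[tid]], st)$count
    native <- count_native_baseline(traces[[tid]])
    data.frame(
      trial_id = tid,
      method = c("shake", "native_baseline", "observed"),
      settings_label = c(st$label, NA_character_, NA_character_),
      counted_steps = as.integer(c(shake, native, trials$observed_steps[i])),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Count every trial under every candidate of a settings grid
#'
#' The calibration-phase workhorse: one `shake` record per grid candidate
#' per trial. With the study's calibration fixture (5 participants x 3
#' trials x 2 platforms at one speed) and a 9-candidate grid this yields
#' the 270 observations per speed that the calibration models are fitted
#' on.
#'
#' @param traces Named list of traces keyed by trial_id.
#' @param trials Trial-metadata data frame.
#' @param grid A [settings_grid()].
#' @return Data frame `trial_id`, `method` (always `"shake"`),
#'   `settings_label`, `counted_steps`.
#' @export
apply_settings_grid <- function(traces, trials, grid) {
  if (!inherits(grid, "settings_grid")) stop("`grid` must be a settings_grid")
  missing_tr <- setdiff(trials$trial_id, names(traces))
  if (length(missing_tr))
    stop("no trace for trial(s): ", paste(missing_tr, collapse = ", "))
  out <- lapply(names(grid), function(lbl) {
    counts <- vapply(trials$trial_id, function(tid)
      detect_steps(traces[[tid]], grid[[lbl]])$count, integer(1))
    data.frame(trial_id = trials$trial_id, method = "shake",
               settings_label = lbl, counted_steps = as.integer(counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
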