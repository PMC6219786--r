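# standard gravity, m/s^2
GRAVITY <- 9.80665

#' Gait signal parameters for a single simulated walking trial
#'
#' Bundles the kinematic and sensor parameters that define one synthetic
#' walking trial. The vertical body-axis acceleration is modelled as gravity
#' plus a sinusoid at the step frequency `speed / step_length`, whose
#' amplitude grows linearly with walking speed (`base_amplitude_coeff *
#' speed`) — reflecting the positive relationship between walking speed and
#' the vertical excursion of the centre of mass — plus optional 2nd/3rd
#' harmonics and i.i.d. Gaussian sensor noise.
#'
#' @param speed Walking speed in m/s. Must be positive.
#' @param step_length Step length in m. Must be positive.
#' @param base_amplitude_coeff Vertical oscillation amplitude per unit
#'   walking speed, (m/s^2)/(m/s). Default 2.0 gives amplitudes of roughly
#'   1.6 m/s^2 at 0.8 m/s and 2.8 m/s^2 at 1.4 m/s, plausible for
#'   pocket-level vertical acceleration during over-ground walking.
#' @param harmonic_weights Numeric vector of length 2: relative amplitudes
#'   of the 2nd and 3rd harmonics of the step frequency (dimensionless
#'   fractions of the fundamental).
#' @param noise_sd Per-axis sensor noise standard deviation, m/s^2.
#' @param sample_rate_hz Accelerometer sampling rate, samples/s. Must be at
#'   least 20 to represent step dynamics.
#' @param ap_ratio Amplitude of the anterior-posterior body-axis
#'   oscillation as a fraction of the vertical amplitude.
#' @param orientation One of `"random"` (a new small random pocket rotation
#'   per trial), `"fixed"` (one rotation drawn from `seed`, reused), or
#'   `"none"` (device axes coincide with body axes).
#' @param tilt_sd_deg Standard deviation of the random pocket tilt angle in
#'   degrees (half-normal, capped at 25 degrees).
#' @param seed Optional RNG seed applied when the trial is simulated.
#'
#' @return An object of class `gait_params`.
#' @seealso [simulate_trial()]
#' @export
gait_params <- function(speed,
                        step_length = 0.70,
                        base_amplitude_coeff = 2.0,
                        harmonic_weights = c(0.2, 0.1),
                        noise_sd = 0.3,
                        sample_rate_hz = 100,
                        ap_ratio = 0.25,
                        orientation = c("random", "fixed", "none"),
                        tilt_sd_deg = 8,
                        seed = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(speed), length(speed) == 1L,
            is.numeric(step_length), length(step_length) == 1L)
  if (!is.finite(speed) || speed <= 0)
    stop("`speed` must be a positive walking speed in m/s (got ", speed, ")")
  if (!is.finite(step_length) || step_length <= 0)
    stop("`step_length` must be a positive length in m (got ", step_length, ")")
  if (!is.finite(sample_rate_hz) || sample_rate_hz < 20)
    stop("`sample_rate_hz` must be >= 20 Hz; lower rates cannot represent ",
         "step dynamics (got ", sample_rate_hz, ")")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0")
  harmonic_weights <- rep_len(as.numeric(harmonic_weights), 2L)
  structure(
    list(speed = speed, step_length = step_length,
         base_amplitude_coeff = base_amplitude_coeff,
         harmonic_weights = harmonic_weights, noise_sd = noise_sd,
         sample_rate_hz = sample_rate_hz, ap_ratio = ap_ratio,
         orientation = orientation, tilt_sd_deg = tilt_sd_deg, seed = seed),
    class = "gait_params")
}

#' Cohort design for a simulated walking study
#'
#' Describes a repeated-measures walking study: every participant walks
#' every distance at both gait speeds (slow < 1 m/s, normal > 1 m/s) on
#' every device platform, `trials_per_cell` times, in randomized order.
#' Participant-level speed and step-length heterogeneity is drawn from the
#' supplied means and SDs; realized speeds are truncated to their
#' category's side of 1 m/s, so every trial respects its nominal speed
#' stratum (the design guarantee that timing gates enforce in over-ground
#' protocols).
#'
#' @param n_participants Number of participants (>= 1).
#' @param distances Course lengths in m (all > 0).
#' @param speed_categories Character subset of `c("slow", "normal")`.
#' @param speed_mean,speed_sd Named numeric vectors (names `slow`,
#'   `normal`): cohort mean and SD of realized walking speed per category,
#'   m/s. Defaults are the cohort values 0.81 +/- 0.09 (slow) and
#'   1.38 +/- 0.16 (normal).
#' @param step_length_mean,step_length_sd Mean and SD of participant step
#'   length, m.
#' @param trials_per_cell Trials per participant x distance x speed x
#'   platform cell (>= 1).
#' @param platforms Character vector of device platform labels.
#' @param gait Optional `gait_params`-like template supplying signal and
#'   sensor parameters (its `speed`, `step_length` and `seed` are ignored);
#'   `NULL` uses the package defaults.
#' @param seed RNG seed making the whole cohort reproducible.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_participants,
                        distances = c(6, 10, 20),
                        speed_categories = c("slow", "normal"),
                        speed_mean = c(slow = 0.81, normal = 1.38),
                        speed_sd = c(slow = 0.09, normal = 0.16),
                        step_length_mean = 0.70,
                        step_length_sd = 0.05,
                        trials_per_cell = 3,
                        platforms = c("ios", "android"),
                        gait = NULL,
                        seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 1)
    stop("`n_participants` must be >= 1")
  if (length(distances) < 1 || any(!is.finite(distances)) || any(distances <= 0))
    stop("all `distances` must be positive course lengths in m")
  if (trials_per_cell < 1)
    stop("`trials_per_cell` must be >= 1")
  speed_categories <- match.arg(speed_categories,
                                c("slow", "normal"), several.ok = TRUE)
  if (!all(speed_categories %in% names(speed_mean)) ||
      !all(speed_categories %in% names(speed_sd)))
    stop("`speed_mean` and `speed_sd` must be named for every speed category")
  if (length(platforms) < 1) stop("at least one platform label is required")
  structure(
    list(n_participants = as.integer(n_participants), distances = distances,
         speed_categories = speed_categories,
         speed_mean = speed_mean, speed_sd = speed_sd,
         step_length_mean = step_length_mean, step_length_sd = step_length_sd,
         trials_per_cell = as.integer(trials_per_cell), platforms = platforms,
         gait = gait, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Shake-service detector settings
#'
#' The two knobs of the shake-service step counter: `sensitivity`, the
#' minimum per-sample acceleration change (m/s^2, evaluated at the
#' detector's internal rate) required to register an event, and
#' `refresh_ms`, the refractory window after a registered event during
#' which further threshold crossings are discarded.
#'
#' @param sensitivity Acceleration-delta threshold, m/s^2 (> 0).
#' @param refresh_ms Refractory period, milliseconds (>= 0).
#' @param detector_rate_hz Internal resampling rate at which consecutive
#'   deltas are evaluated. All traces are linearly resampled to this rate
#'   before delta evaluation so a given `sensitivity` means the same thing
#'   regardless of the trace's native sampling rate. Default 10 Hz, which
#'   places per-sample deltas of walking-scale signals on the 1.0-2.5
#'   m/s^2 scale of the published settings grid.
#' @param label Optional label; defaults to `"<sensitivity>/<refresh_ms>"`,
#'   e.g. `"2.5/450"`.
#'
#' @return An object of class `detector_settings`.
#' @export
detector_settings <- function(sensitivity, refresh_ms,
                              detector_rate_hz = 10, label = NULL) {
  if (!is.finite(sensitivity) || sensitivity <= 0)
    stop("`sensitivity` must be > 0 (m/s^2)")
  if (!is.finite(refresh_ms) || refresh_ms < 0)
    stop("`refresh_ms` must be >= 0 (milliseconds)")
  if (!is.finite(detector_rate_hz) || detector_rate_hz <= 0)
    stop("`detector_rate_hz` must be > 0")
  if (is.null(label))
    label <- paste0(format(sensitivity, trim = TRUE), "/",
                    format(refresh_ms, trim = TRUE))
  structure(list(sensitivity = sensitivity, refresh_ms = refresh_ms,
                 detector_rate_hz = detector_rate_hz, label = label),
            class = "detector_settings")
}

#' Build a grid of candidate detector settings
#'
#' Either crosses vectors of sensitivities and refresh times (the usual
#' calibration menu) or bundles a list of ready-made [detector_settings()]
#' candidates. Labels must be unique.
#'
#' @param sensitivities Numeric vector of sensitivity candidates, or a list
#'   of `detector_settings` objects (in which case `refresh_times` is
#'   ignored).
#' @param refresh_times Numeric vector of refresh-time candidates, ms.
#' @param detector_rate_hz Internal detector rate shared by all candidates.
#' @return An object of class `settings_grid`: a named list of
#'   `detector_settings`.
#' @examples
#' settings_grid(c(1.5, 2.0, 2.5), c(400, 450, 500))
#' @export
settings_grid <- function(sensitivities, refresh_times = NULL,
                          detector_rate_hz = 10) {
  if (is.list(sensitivities) &&
      all(vapply(sensitivities, inherits, TRUE, "detector_settings"))) {
    cands <- sensitivities
  } else {
    if (is.null(refresh_times))
      stop("`refresh_times` is required when crossing numeric candidates")
    combos <- expand.grid(refresh_ms = refresh_times,
                          sensitivity = sensitivities)[, 2:1]
    cands <- lapply(seq_len(nrow(combos)), function(i)
      detector_settings(combos$sensitivity[i], combos$refresh_ms[i],
                        detector_rate_hz = detector_rate_hz))
  }
  if (length(cands) == 0) stop("a settings grid must be non-empty")
  labels <- vapply(cands, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("settings grid labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  names(cands) <- labels
  structure(cands, class = "settings_grid")
}

#' Default calibration grids per walking speed
#'
#' The nine-candidate sensitivity x refresh-time menus evaluated during
#' calibration: `{1.0, 1.5, 2.0} x {400, 450, 500}` ms for slow walking
#' (< 1 m/s) and `{1.5, 2.0, 2.5} x {400, 450, 500}` ms for normal walking
#' (> 1 m/s). Slow walking produces smaller vertical accelerations, so its
#' menu reaches lower sensitivities.
#'
#' @param speed_category `"slow"` or `"normal"`.
#' @param detector_rate_hz Internal detector rate.
#' @return A [settings_grid()].
#' @export
default_grid <- function(speed_category = c("slow", "normal"),
                         detector_rate_hz = 10) {
  speed_category <- match.arg(speed_category)
  sens <- if (speed_category == "slow") c(1.0, 1.5, 2.0) else c(1.5, 2.0, 2.5)
  settings_grid(sens, c(400, 450, 500), detector_rate_hz = detector_rate_hz)
}

#' Default per-speed detector settings
#'
#' The settings pair used when no calibration is run: sensitivity/refresh
#' 1.5/500 for slow and 2.5/450 for normal walking (the combination
#' selected in the study this tool reproduces).
#'
#' @param detector_rate_hz Internal detector rate.
#' @return Named list with elements `slow` and `normal`.
#' @export
default_settings <- function(detector_rate_hz = 10) {
  list(slow = detector_settings(1.5, 500, detector_rate_hz),
       normal = detector_settings(2.5, 450, detector_rate_hz))
}

#' @export
print.detector_settings <- function(x, ...) {
  cat("<detector_settings> ", x$label,
      "  (sensitivity ", x$sensitivity, " m/s^2, refresh ", x$refresh_ms,
      " ms, detector rate ", x$detector_rate_hz, " Hz)\n", sep = "")
  invisible(x)
}

#' @export
print.settings_grid <- function(x, ...) {
  cat("<settings_grid> ", length(x), " candidates: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_participants, " participants x ",
      length(x$distances), " distances x ",
      length(x$speed_categories), " speeds x ",
      length(x$platforms), " platforms x ",
      x$trials_per_cell, " trials\n", sep = "")
  invisible(x)
}
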