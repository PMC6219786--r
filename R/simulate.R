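# Truncated-normal draws via inverse-CDF, vectorized.
# side = "below": x < bound; side = "above": x > bound.
rtruncnorm_side <- function(n, mean, sd, bound, side) {
  if (sd <= 0) return(rep(mean, n))
  p <- pnorm(bound, mean, sd)
  u <- runif(n)
  q <- if (side == "below") u * p else p + u * (1 - p)
  # guard against q hitting 0/1 in floating point
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  qnorm(q, mean, sd)
}

# Rodrigues rotation matrix about unit axis `u` by `theta` radians.
rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Small random pocket rotation: half-normal tilt angle (deg), capped.
random_pocket_rotation <- function(tilt_sd_deg, cap_deg = 25) {
  ang <- min(abs(rnorm(1, 0, tilt_sd_deg)), cap_deg) * pi / 180
  ax <- rnorm(3)
  rotation_matrix(ax, ang)
}

#' Simulate one over-ground walking trial
#'
#' Generates a tri-axial accelerometer trace for a straight over-ground
#' walk of `distance` metres, together with its trial metadata including
#' the exact ground-truth step count. The walker stops on the step that
#' crosses the finish line, so a partial final step counts as a full step:
#' `observed_steps = ceiling(distance / step_length)`.
#'
#' The body-frame signal is gravity plus a vertical sinusoid at the step
#' frequency `f = speed / step_length`, amplitude
#' `A = base_amplitude_coeff * speed`, optional 2nd/3rd harmonics, a
#' smaller anterior-posterior oscillation, amplitude ramps over one step
#' period at the start and end of the walk (gait initiation/termination
#' transients), a per-trial pocket rotation mapping body axes to device
#' axes, and i.i.d. Gaussian noise per axis. The constant-amplitude core
#' of the trace lasts exactly `N / f` seconds (N oscillation cycles = N
#' steps); one ramp period is prepended and appended.
#'
#' @param params A [gait_params()] object.
#' @param distance Course length in m (> 0).
#' @param trial_id,participant_id,platform,speed_category,trial_index
#'   Metadata carried into the returned trial row.
#' @return A list with elements `trace` (data frame `t`, `ax`, `ay`, `az`
#'   of class `accel_trace`, with attributes `trial_id` and `device`) and
#'   `trial` (one-row data frame: trial_id, participant_id, platform,
#'   distance_m, speed_category, realized_speed_mps, trial_index,
#'   observed_steps).
#' @examples
#' st <- simulate_trial(gait_params(speed = 1.0, step_length = 0.5, seed = 1),
#'                      distance = 6)
#' st$trial$observed_steps   # 12 steps: 6 m at 0.5 m per step
#' @export
simulate_trial <- function(params, distance,
                           trial_id = "trial-1", participant_id = "p1",
                           platform = "ios", speed_category = NULL,
                           trial_index = 1L) {
  if (!inherits(params, "gait_params"))
    stop("`params` must be a gait_params object")
  if (!is.finite(distance) || distance <= 0)
    stop("`distance` must be a positive course length in m (got ",
         distance, ")")
  if (!is.null(params$seed)) set.seed(params$seed)

  v <- params$speed
  L <- params$step_length
  n_steps <- as.integer(ceiling(distance / L))
  f <- v / L                        # step frequency, Hz
  P <- 1 / f                        # step period, s
  A <- params$base_amplitude_coeff * v
  w <- params$harmonic_weights
  fs <- params$sample_rate_hz

  total <- n_steps * P + 2 * P      # core walk + initiation/termination ramps
  t <- seq(0, total, by = 1 / fs)
  env <- pmin(1, pmin(t, total - t) / P)
  env[env < 0] <- 0
  theta <- 2 * pi * f * (t - P) - pi / 2   # core starts at a trough
  osc <- sin(theta) + w[1] * sin(2 * theta) + w[2] * sin(3 * theta)
  vert <- A * env * osc
  ap <- params$ap_ratio * A * env * sin(theta + pi / 3)

  R <- switch(params$orientation,
              none = diag(3),
              fixed = ,
              random = random_pocket_rotation(params$tilt_sd_deg))
  body <- rbind(ap, 0, GRAVITY + vert)     # 3 x n: AP, ML, vertical
  dev <- R %*% body
  n <- length(t)
  noise <- matrix(rnorm(3 * n, 0, params$noise_sd), 3, n)
  dev <- dev + noise

  if (is.null(speed_category)) speed_category <- if (v < 1) "slow" else "normal"
  trace <- data.frame(t = t, ax = dev[1, ], ay = dev[2, ], az = dev[3, ])
  attr(trace, "trial_id") <- trial_id
  attr(trace, "device") <- platform
  class(trace) <- c("accel_trace", "data.frame")
  trial <- data.frame(
    trial_id = trial_id, participant_id = participant_id, platform = platform,
    distance_m = distance, speed_category = speed_category,
    realized_speed_mps = v, trial_index = as.integer(trial_index),
    observed_steps = n_steps, stringsAsFactors = FALSE)
  list(trace = trace, trial = trial)
}

#' Simulate a full walking-study cohort
#'
#' Draws a personal step length and per-category walking speeds for every
#' participant, then simulates `trials_per_cell` trials for every
#' participant x distance x speed-category x platform cell, in randomized
#' per-participant order. Realized trial speeds are truncated-normal draws
#' centred on the participant's category speed, always on their category's
#' side of 1 m/s. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `traces` (named list of `accel_trace`
#'   keyed by trial_id) and `trials` (data frame of trial metadata, one
#'   row per trial, in each participant's randomized walk order).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(
#'   n_participants = 2, distances = 10, speed_categories = "normal",
#'   platforms = "ios", seed = 7))
#' nrow(cohort$trials)   # 2 participants x 3 trials
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec")
  set.seed(spec$seed)
  gait_template <- spec$gait
  if (is.null(gait_template)) gait_template <- gait_params(speed = 1)

  traces <- list()
  trials <- vector("list", spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    pid <- sprintf("P%03d", i)
    step_len <- max(0.3, rnorm(1, spec$step_length_mean, spec$step_length_sd))
    # participant-level category speed: half the category variance;
    # per-trial jitter carries the rest, so marginal SD matches the spec
    pspeed <- sapply(spec$speed_categories, function(cat) {
      rtruncnorm_side(1, spec$speed_mean[[cat]], 0.5 * spec$speed_sd[[cat]],
                      bound = 1,
                      side = if (cat == "slow") "below" else "above")
    })
    names(pspeed) <- spec$speed_categories

    cells <- expand.grid(distance = spec$distances,
                         speed_category = spec$speed_categories,
                         platform = spec$platforms,
                         trial_index = seq_len(spec$trials_per_cell),
                         stringsAsFactors = FALSE)
    cells <- cells[sample.int(nrow(cells)), , drop = FALSE]  # randomized order

    rows <- vector("list", nrow(cells))
    for (k in seq_len(nrow(cells))) {
      cat_k <- cells$speed_category[k]
      sp <- rtruncnorm_side(1, pspeed[[cat_k]],
                            sqrt(0.75) * spec$speed_sd[[cat_k]], bound = 1,
                            side = if (cat_k == "slow") "below" else "above")
      tid <- sprintf("%s-%s-%gm-%s-t%d", pid, cells$platform[k],
                     cells$distance[k], cat_k, cells$trial_index[k])
      gp <- gait_template
      gp$speed <- sp
      gp$step_length <- step_len
      gp$seed <- NULL
      st <- simulate_trial(gp, cells$distance[k], trial_id = tid,
                           participant_id = pid,
                           platform = cells$platform[k],
                           speed_category = cat_k,
                           trial_index = cells$trial_index[k])
      traces[[tid]] <- st$trace
      rows[[k]] <- st$trial
    }
    trials[[i]] <- do.call(rbind, rows)
  }
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  list(traces = traces, trials = trials)
}
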