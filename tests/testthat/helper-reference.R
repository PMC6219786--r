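# Independent naive reference for the shake detector: resamples with the
# same linear-interpolation contract, then scans sample by sample keeping
# the time of the last registered event. Deliberately written as a plain
# one-pass loop, sharing no event logic with the package implementation.
reference_detect <- function(trace, settings) {
  t <- trace$t
  grid <- seq(t[1], t[length(t)], by = 1 / settings$detector_rate_hz)
  ax <- approx(t, trace$ax, xout = grid)$y
  ay <- approx(t, trace$ay, xout = grid)$y
  az <- approx(t, trace$az, xout = grid)$y
  refractory <- settings$refresh_ms / 1000
  last <- -Inf
  times <- numeric(0)
  for (i in seq_along(grid)[-1]) {
    d <- max(abs(ax[i] - ax[i - 1]), abs(ay[i] - ay[i - 1]),
             abs(az[i] - az[i - 1]))
    if (d > settings$sensitivity && grid[i] - last >= refractory) {
      times <- c(times, grid[i])
      last <- grid[i]
    }
  }
  list(count = length(times), event_times = times)
}

# Random jittery trace for property tests: random-walk axes so deltas of
# every magnitude occur; optionally irregular timestamps.
random_trace <- function(n = sample(2:1000, 1), regular = runif(1) < 0.5) {
  dt <- if (regular) rep(1 / runif(1, 20, 120), n - 1) else
    runif(n - 1, 0.005, 0.05)
  t <- c(0, cumsum(dt))
  mk <- function() cumsum(rnorm(n, 0, runif(1, 0.05, 0.8)))
  tr <- data.frame(t = t, ax = mk(), ay = mk(), az = mk())
  class(tr) <- c("accel_trace", "data.frame")
  tr
}

random_settings <- function() {
  detector_settings(
    sensitivity = runif(1, 0.05, 1.5),
    refresh_ms = sample(c(0, 50, 100, 250, 400, 600), 1),
    detector_rate_hz = sample(c(10, 25, 60), 1))
}

# Flat trace at a given rate (useful for hand-built detector inputs).
flat_trace <- function(n, rate = 10, value = 0) {
  tr <- data.frame(t = seq(0, by = 1 / rate, length.out = n),
                   ax = rep(value, n), ay = rep(value, n),
                   az = rep(value, n))
  class(tr) <- c("accel_trace", "data.frame")
  tr
}
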