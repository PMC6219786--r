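test_that("a constant trace produces no events at any settings", {
  tr <- flat_trace(200, rate = 10, value = 5)
  for (s in list(detector_settings(0.1, 0), detector_settings(2.5, 450)))
    expect_identical(detect_steps(tr, s)$count, 0L)
})

test_that("the refractory window absorbs a second jolt 100 ms later", {
  # two supra-threshold upward jumps on consecutive 10 Hz samples
  tr <- flat_trace(30, rate = 10)
  tr$az[15:30] <- 3   # delta 3 at sample 15
  tr$az[16:30] <- 6   # delta 3 again at sample 16, 100 ms later
  expect_identical(detect_steps(tr, detector_settings(1, 400))$count, 1L)
  # with no refractory both jolts count
  expect_identical(detect_steps(tr, detector_settings(1, 0))$count, 2L)
})

test_that("square-wave toggles are counted once each when spaced beyond the refractory", {
  sens <- 1.2
  rate <- 50
  t <- seq(0, 10, by = 1 / rate)
  x <- 2 * sens * (floor(t / 0.6) %% 2)   # toggles every 600 ms
  tr <- data.frame(t = t, ax = x, ay = 0, az = 0)
  # independent enumeration: toggle instants in (0, 10], spacing 600 > 400 ms
  expected <- sum(diff(floor(t / 0.6) %% 2) != 0)
  got <- detect_steps(tr, detector_settings(sens, 400,
                                            detector_rate_hz = rate))
  expect_identical(got$count, as.integer(expected))
  expect_true(all(diff(got$event_times) >= 0.4 - 1e-12))
})

test_that("detector matches the naive one-pass reference on random traces", {
  set.seed(23)
  for (k in 1:200) {
    tr <- random_trace(n = sample(2:400, 1))
    st <- random_settings()
    a <- suppressWarnings(detect_steps(tr, st))
    b <- suppressWarnings(reference_detect(tr, st))
    expect_identical(a$count, b$count)
    expect_equal(a$event_times, b$event_times)
  }
})

test_that("event count respects the refractory bound", {
  set.seed(31)
  for (k in 1:100) {
    tr <- random_trace(n = sample(3:500, 1))
    st <- detector_settings(runif(1, 0.05, 1), sample(c(100, 250, 400), 1),
                            detector_rate_hz = sample(c(10, 60), 1))
    got <- suppressWarnings(detect_steps(tr, st))
    dur <- max(tr$t) - min(tr$t)
    expect_lte(got$count, floor(dur / (st$refresh_ms / 1000)) + 1)
  }
})

test_that("with no refractory, raising sensitivity never raises the count", {
  set.seed(37)
  for (k in 1:60) {
    tr <- random_trace(n = sample(10:400, 1))
    s1 <- runif(1, 0.05, 0.8)
    s2 <- s1 + runif(1, 0.05, 1)
    rate <- sample(c(10, 60), 1)
    c1 <- detect_steps(tr, detector_settings(s1, 0, rate))$count
    c2 <- detect_steps(tr, detector_settings(s2, 0, rate))$count
    expect_lte(c2, c1)
  }
})

test_that("the detector sees only deltas: constant offsets do not matter", {
  set.seed(41)
  for (k in 1:20) {
    tr <- random_trace(n = 150)
    st <- random_settings()
    tr2 <- tr
    off <- rnorm(3, 0, 50)
    tr2$ax <- tr2$ax + off[1]; tr2$ay <- tr2$ay + off[2]
    tr2$az <- tr2$az + off[3]
    expect_identical(detect_steps(tr, st)$count, detect_steps(tr2, st)$count)
  }
})

test_that("scaling accelerations and sensitivity together leaves counts unchanged", {
  set.seed(43)
  for (cc in c(0.1, 3, 42)) {
    tr <- random_trace(n = 300)
    st <- random_settings()
    tr2 <- tr
    tr2[c("ax", "ay", "az")] <- tr2[c("ax", "ay", "az")] * cc
    st2 <- detector_settings(st$sensitivity * cc, st$refresh_ms,
                             st$detector_rate_hz)
    expect_identical(detect_steps(tr, st)$count, detect_steps(tr2, st2)$count)
  }
})

test_that("degenerate traces are handled loudly", {
  tr <- flat_trace(1)
  expect_warning(res <- detect_steps(tr, detector_settings(1, 400)),
                 "fewer than 2 samples")
  expect_identical(res$count, 0L)
  bad <- data.frame(t = c(0, 2, 1), ax = 0, ay = 0, az = 0)
  expect_error(detect_steps(bad, detector_settings(1, 400)),
               "strictly increasing")
})

test_that("baseline counter is accurate when amplitude clears its fixed threshold", {
  expect_identical(count_native_baseline(flat_trace(600, rate = 100)), 0L)
  # noiseless normal-speed walk: large amplitude, counts within one step
  st <- simulate_trial(gait_params(speed = 1.38, noise_sd = 0,
                                   orientation = "none"), distance = 20)
  n <- count_native_baseline(st$trace)
  expect_lte(abs(n - st$trial$observed_steps), 1)
})

test_that("baseline counter undercounts slow walks below its fixed threshold", {
  # slow-walk amplitude (~1.7 m/s^2 filtered) sits under the frozen
  # 2.2 m/s^2 peak threshold
  st <- simulate_trial(gait_params(speed = 0.81, noise_sd = 0,
                                   orientation = "none"), distance = 20)
  expect_lt(count_native_baseline(st$trace), st$trial$observed_steps)
})

test_that("count_trials emits shake, baseline and observed per trial", {
  co <- simulate_cohort(cohort_spec(2, distances = c(6, 10),
                                    platforms = "ios", seed = 53))
  # 2 participants x 2 distances x 2 speeds x 3 trials = 24 trials
  recs <- count_trials(co$traces, co$trials, default_settings())
  expect_identical(nrow(recs), nrow(co$trials) * 3L)
  obs <- recs[recs$method == "observed", ]
  expect_identical(
    obs$counted_steps[match(co$trials$trial_id, obs$trial_id)],
    co$trials$observed_steps)
  expect_true(all(!is.na(recs$settings_label[recs$method == "shake"])))
  expect_true(all(is.na(recs$settings_label[recs$method != "shake"])))
  # deterministic
  expect_identical(recs, count_trials(co$traces, co$trials,
                                      default_settings()))
})

test_that("count_trials rejects missing traces or missing settings by name", {
  co <- simulate_cohort(cohort_spec(2, distances = 6, platforms = "ios",
                                    seed = 54))
  expect_error(count_trials(co$traces[-1], co$trials, default_settings()),
               co$trials$trial_id[co$trials$trial_id %in%
                                    setdiff(co$trials$trial_id,
                                            names(co$traces[-1]))][1],
               fixed = TRUE)
  expect_error(count_trials(co$traces, co$trials,
                            list(slow = detector_settings(1.5, 500))),
               "normal")
})
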