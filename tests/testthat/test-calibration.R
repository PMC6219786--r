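test_that("absolute step difference is symmetric and directionless", {
  expect_identical(abs_step_difference(30, 28), 2L)
  expect_identical(abs_step_difference(28, 30), 2L)
  expect_identical(abs_step_difference(17, 17), 0L)
  expect_identical(abs_step_difference(c(5, 9), c(9, 5)), c(4L, 4L))
  expect_error(abs_step_difference(-1, 3), "non-negative")
})

test_that("grid evaluation enumerates the calibration design", {
  grid <- default_grid("normal")
  trials <- do.call(rbind, lapply(c("ios", "android"), function(pf) {
    tt <- toy_trials(5, 3, observed = 28, platform = pf)
    tt$trial_id <- paste0(pf, "-", tt$trial_id)
    tt
  }))
  # every setting counts every trial perfectly except one, off by 2
  recs <- do.call(rbind, lapply(names(grid), function(lbl)
    records_with_errors(trials, "shake",
                        err = if (lbl == "2/400") 2 else 0,
                        settings_label = lbl)))
  expect_identical(nrow(recs), 270L)  # 5 x 9 x 3 x 2 observations
  errs <- evaluate_grid(recs, trials, grid, "normal")
  expect_identical(nrow(errs), 9L)
  expect_true(all(errs$n_obs == 30L))  # 5 participants x 3 trials x 2 phones
  expect_equal(errs$mean_abs_diff[errs$settings_label == "2/400"], 2)
  expect_equal(errs$sd_abs_diff[errs$settings_label == "2/400"], 0)
  expect_true(all(errs$mean_abs_diff[errs$settings_label != "2/400"] == 0))
})

test_that("missing setting-by-trial combinations are reported by label", {
  grid <- settings_grid(c(1.5, 2.5), 450)
  trials <- toy_trials(2, 2)
  recs <- records_with_errors(trials, "shake", 0, "1.5/450")
  expect_error(evaluate_grid(recs, trials, grid, "normal"), "2.5/450")
})

test_that("setting comparison uses the empirical best as referent with IRR 1", {
  set.seed(83)
  trials <- toy_trials(6, 3)
  recs <- rbind(
    records_with_errors(trials, "shake", rpois(18, 1), "good"),
    records_with_errors(trials, "shake", rpois(18, 4) + 1, "bad"))
  cmp <- compare_settings(recs, trials, "normal")
  expect_identical(cmp$referent_label, "good")
  ref_row <- cmp$irr[cmp$irr$settings_label == "good", ]
  expect_equal(ref_row$irr, 1)
  expect_identical(ref_row$note, "referent")
  bad_row <- cmp$irr[cmp$irr$settings_label == "bad", ]
  expect_gt(bad_row$irr, 1)
  expect_lt(bad_row$p_value, 0.05)
})

test_that("settings with identical error distributions are statistically indistinguishable", {
  set.seed(89)
  # enough clusters that robust SEs reach near-nominal coverage
  trials <- toy_trials(30, 3)
  err <- rpois(90, 2)
  recs <- rbind(records_with_errors(trials, "shake", err, "s1"),
                records_with_errors(trials, "shake", err + 0L, "s2"))
  # identical errors: point estimate exactly 1
  cmp <- compare_settings(recs, trials, "normal", referent_label = "s1")
  expect_equal(cmp$irr$irr[cmp$irr$settings_label == "s2"], 1,
               tolerance = 1e-8)
  # same distribution, independent draws: CI covers 1
  set.seed(90)
  recs2 <- rbind(records_with_errors(trials, "shake", rpois(90, 2), "s1"),
                 records_with_errors(trials, "shake", rpois(90, 2), "s2"))
  cmp2 <- compare_settings(recs2, trials, "normal")
  other <- cmp2$irr[cmp2$irr$note != "referent", ]
  expect_true(other$ci_lower < 1 && 1 < other$ci_upper)
})

test_that("singleton clusters make the setting comparison an ordinary NB fit", {
  set.seed(97)
  trials <- toy_trials(40, 1)   # one trial per participant
  e1 <- rpois(40, 2); e2 <- rpois(40, 5) + 1
  recs <- rbind(records_with_errors(trials, "shake", e1, "s1"),
                records_with_errors(trials, "shake", e2, "s2"))
  cmp <- compare_settings(recs, trials, "normal", referent_label = "s1")
  d <- data.frame(diff = c(e1, e2), lbl = rep(c("s1", "s2"), each = 40))
  oracle <- suppressWarnings(MASS::glm.nb(diff ~ lbl, d))
  expect_equal(log(cmp$irr$irr[cmp$irr$settings_label == "s2"]),
               coef(oracle)[["lbls2"]], tolerance = 1e-6)
})

test_that("perfect settings are flagged rather than modelled", {
  set.seed(101)
  trials <- toy_trials(5, 3)
  recs <- rbind(records_with_errors(trials, "shake", 0L, "perfect"),
                records_with_errors(trials, "shake", rpois(15, 3) + 1, "noisy"))
  cmp <- compare_settings(recs, trials, "normal")
  expect_identical(cmp$referent_label, "perfect")
  expect_match(cmp$irr$note[cmp$irr$settings_label == "perfect"],
               "no contrast fitted")
  expect_null(cmp$fit)
})

test_that("selection minimizes the mean error with the documented tie-break", {
  grid <- settings_grid(c(1.5, 2.0, 2.5), c(400, 450))
  errs <- data.frame(
    settings_label = names(grid), speed_category = "normal",
    n_obs = 30, mean_abs_diff = c(3, 1.4, 2, 1.4, 5, 6), sd_abs_diff = 1,
    stringsAsFactors = FALSE)
  sel <- select_settings(errs, grid)
  # tie between 1.5/450 (1.4) and 2/400 (1.4): lower sensitivity wins
  expect_identical(sel$settings_label, "1.5/450")
  expect_true(sel$tie_broken)
  expect_equal(sel$mean_abs_diff, 1.4)
  # refresh breaks a same-sensitivity tie
  errs$mean_abs_diff <- c(1.4, 1.4, 3, 4, 5, 6)
  sel <- select_settings(errs, grid)
  expect_identical(sel$settings_label, "1.5/400")
  # single-candidate grid selects itself
  g1 <- settings_grid(2.5, 450)
  sel1 <- select_settings(data.frame(settings_label = "2.5/450",
                                     speed_category = "normal", n_obs = 3,
                                     mean_abs_diff = 9, sd_abs_diff = 1),
                          g1)
  expect_identical(sel1$settings_label, "2.5/450")
})

test_that("full calibration selects the per-speed error minimizer", {
  co <- calibration_cohort(n = 4, platforms = "ios", seed = 103)
  grids <- both_grids()
  recs <- do.call(rbind, lapply(names(grids), function(sp)
    apply_settings_grid(co$traces,
                        co$trials[co$trials$speed_category == sp, ],
                        grids[[sp]])))
  cal <- run_calibration(recs, co$trials, grids)
  for (sp in c("slow", "normal")) {
    errs <- cal$per_speed[[sp]]$errors
    sel <- cal$selected[cal$selected$speed_category == sp, ]
    expect_true(all(sel$mean_abs_diff <= errs$mean_abs_diff))
    expect_equal(cal$per_speed[[sp]]$irr$irr[
      cal$per_speed[[sp]]$irr$settings_label ==
        cal$per_speed[[sp]]$referent_label], 1)
  }
})

test_that("calibration is equivariant to a common acceleration/sensitivity scale", {
  co <- calibration_cohort(n = 3, platforms = "ios", seed = 107)
  grids <- both_grids()
  cc <- 2.7
  traces2 <- lapply(co$traces, function(tr) {
    tr[c("ax", "ay", "az")] <- tr[c("ax", "ay", "az")] * cc
    tr
  })
  grids2 <- lapply(grids, function(g)
    settings_grid(lapply(g, function(s) {
      s2 <- detector_settings(s$sensitivity * cc, s$refresh_ms,
                              s$detector_rate_hz, label = s$label)
      s2
    })))
  for (sp in c("slow", "normal")) {
    tr_sp <- co$trials[co$trials$speed_category == sp, ]
    r1 <- apply_settings_grid(co$traces, tr_sp, grids[[sp]])
    r2 <- apply_settings_grid(traces2, tr_sp, grids2[[sp]])
    expect_identical(r1$counted_steps, r2$counted_steps)
    e1 <- evaluate_grid(r1, co$trials, grids[[sp]], sp)
    e2 <- evaluate_grid(r2, co$trials, grids2[[sp]], sp)
    expect_identical(e1$mean_abs_diff, e2$mean_abs_diff)
    expect_identical(select_settings(e1, grids[[sp]])$settings_label,
                     select_settings(e2, grids2[[sp]])$settings_label)
  }
})
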