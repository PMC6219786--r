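#' Absolute step difference
#'
#' The accuracy metric used throughout: the absolute difference between a
#' counted and the observed (ground-truth) step count — "off by" steps in
#' either direction, with no directionality.
#'
#' @param counted,observed Non-negative integer step counts (vectorized).
#' @return Non-negative integer vector `|counted - observed|`.
#' @examples
#' abs_step_difference(30, 28)  # 2
#' abs_step_difference(28, 30)  # 2, symmetric
#' @export
abs_step_difference <- function(counted, observed) {
  if (any(!is.finite(counted)) || any(!is.finite(observed)) ||
      any(counted < 0) || any(observed < 0))
    stop("step counts must be non-negative")
  as.integer(abs(counted - observed))
}

# join grid records with trials of one speed category and attach diffs
calibration_frame <- function(records, trials, speed_category) {
  tr <- trials[trials$speed_category == speed_category, , drop = FALSE]
  if (nrow(tr) == 0)
    stop("no trials with speed_category ", speed_category)
  d <- merge(records[records$method == "shake", , drop = FALSE],
             tr[, c("trial_id", "participant_id", "observed_steps")],
             by = "trial_id")
  d$abs_diff <- abs_step_difference(d$counted_steps, d$observed_steps)
  d
}

#' Per-setting error summary over a calibration grid
#'
#' Aggregates the absolute step difference of every grid candidate over
#' all trials of one speed category: the per-setting mean +/- SD error
#' table that drives setting selection.
#'
#' @param records Long-format step-count records containing one `shake`
#'   row per grid candidate per trial (see [apply_settings_grid()]).
#' @param trials Trial-metadata data frame.
#' @param grid The [settings_grid()] that was evaluated.
#' @param speed_category Which speed stratum to summarize.
#' @return Data frame `settings_label`, `speed_category`, `n_obs`,
#'   `mean_abs_diff`, `sd_abs_diff`, one row per grid candidate, in grid
#'   order. SD is the sample SD (n-1 denominator).
#' @export
evaluate_grid <- function(records, trials, grid, speed_category) {
  if (!inherits(grid, "settings_grid")) stop("`grid` must be a settings_grid")
  d <- calibration_frame(records, trials, speed_category)
  tr_ids <- trials$trial_id[trials$speed_category == speed_category]
  missing <- names(grid)[vapply(names(grid), function(lbl)
    !all(tr_ids %in% d$trial_id[d$settings_label == lbl]), TRUE)]
  if (length(missing))
    stop("records are missing (setting x trial) combinations for: ",
         paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(names(grid), function(lbl) {
    x <- d$abs_diff[d$settings_label == lbl]
    data.frame(settings_label = lbl, speed_category = speed_category,
               n_obs = length(x), mean_abs_diff = mean(x),
               sd_abs_diff = if (length(x) > 1) sd(x) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare grid settings by cluster-adjusted negative binomial regression
#'
#' Fits a marginal NB model (GEE, exchangeable working correlation,
#' clustered on participant, robust SEs) of the absolute step difference
#' on the setting indicator, with the empirically best setting (minimum
#' mean absolute difference, unless overridden) as the referent. Each
#' non-referent setting's IRR is its expected error relative to the
#' referent, so IRR > 1 means "worse than the best setting".
#'
#' Settings whose differences are all zero would make the log-linear
#' contrast degenerate; such rows are flagged `"perfect - no contrast
#' fitted"` and excluded from the model.
#'
#' @param records,trials As for [evaluate_grid()].
#' @param speed_category Speed stratum to model.
#' @param referent_label Referent setting; `NULL` picks the empirical
#'   minimizer of the mean absolute difference.
#' @param cluster Name of the clustering column in `trials`.
#' @return List with `irr` (data frame: `settings_label`, `irr`,
#'   `ci_lower`, `ci_upper`, `p_value`, `note`; referent row has IRR 1),
#'   `referent_label`, and `fit` (the [nbgee()] object, or `NULL` when no
#'   contrast could be fitted).
#' @export
compare_settings <- function(records, trials, speed_category,
                             referent_label = NULL,
                             cluster = "participant_id") {
  d <- calibration_frame(records, trials, speed_category)
  if (length(unique(d[[cluster]])) < 2)
    stop("at least 2 clusters are required for a GEE fit")
  means <- tapply(d$abs_diff, d$settings_label, mean)
  labels <- names(means)
  if (is.null(referent_label)) {
    referent_label <- labels[which.min(means)]
  } else if (!referent_label %in% labels) {
    stop("referent_label ", referent_label, " not present in records")
  }
  zero_labels <- labels[tapply(d$abs_diff, d$settings_label,
                               function(x) all(x == 0))]
  model_labels <- setdiff(labels, setdiff(zero_labels, referent_label))

  fit <- NULL
  irr_rows <- data.frame(settings_label = labels, irr = NA_real_,
                         ci_lower = NA_real_, ci_upper = NA_real_,
                         p_value = NA_real_, note = "",
                         stringsAsFactors = FALSE)
  irr_rows$irr[irr_rows$settings_label == referent_label] <- 1
  irr_rows$note[irr_rows$settings_label == referent_label] <- "referent"
  perf <- setdiff(zero_labels, referent_label)
  irr_rows$note[irr_rows$settings_label %in% perf] <-
    "perfect - no contrast fitted"

  if (referent_label %in% zero_labels && length(model_labels) > 1) {
    irr_rows$note[irr_rows$settings_label == referent_label] <-
      "referent (all-zero error) - no contrast fitted"
  } else if (length(model_labels) > 1) {
    dm <- d[d$settings_label %in% model_labels, , drop = FALSE]
    dm$settings_label <- relevel(factor(dm$settings_label), referent_label)
    fit <- nbgee(abs_diff ~ settings_label, dm, id = dm[[cluster]])
    if (!fit$converged)
      warning("NB-GEE setting comparison did not converge for ",
              speed_category, " speed; estimates reported with diagnostics")
    it <- irr_table(fit)
    it <- it[it$term != "(Intercept)", , drop = FALSE]
    it$settings_label <- sub("^settings_label", "", it$term)
    for (k in seq_len(nrow(it))) {
      j <- which(irr_rows$settings_label == it$settings_label[k])
      irr_rows$irr[j] <- it$irr[k]
      irr_rows$ci_lower[j] <- it$ci_lower[k]
      irr_rows$ci_upper[j] <- it$ci_upper[k]
      irr_rows$p_value[j] <- it$p_value[k]
    }
    if (fit$family_used == "poisson")
      irr_rows$note[irr_rows$note == ""] <-
        "no overdispersion - Poisson GEE fallback"
  }
  list(irr = irr_rows, referent_label = referent_label, fit = fit)
}

#' Select the best detector settings from a calibration error table
#'
#' Picks the setting with the minimal mean absolute step difference.
#' Ties are broken toward the lower sensitivity, then the lower refresh
#' time (favouring detection of weaker signals); when a tie was broken
#' the result says so.
#'
#' @param errors Error table from [evaluate_grid()] (one speed category).
#' @param grid The [settings_grid()] the labels refer to (supplies the
#'   numeric sensitivity/refresh values used for tie-breaking).
#' @return One-row data frame: `speed_category`, `settings_label`,
#'   `sensitivity`, `refresh_ms`, `mean_abs_diff`, `tie_broken`.
#' @export
select_settings <- function(errors, grid) {
  if (nrow(errors) == 0) stop("empty error table")
  sens <- vapply(errors$settings_label, function(l) grid[[l]]$sensitivity, 0)
  refr <- vapply(errors$settings_label, function(l) grid[[l]]$refresh_ms, 0)
  best <- min(errors$mean_abs_diff)
  cand <- which(errors$mean_abs_diff == best)
  tie <- length(cand) > 1
  if (tie) {
    ord <- order(sens[cand], refr[cand])
    cand <- cand[ord]
  }
  i <- cand[1]
  data.frame(speed_category = errors$speed_category[i],
             settings_label = errors$settings_label[i],
             sensitivity = sens[i], refresh_ms = refr[i],
             mean_abs_diff = errors$mean_abs_diff[i], tie_broken = tie,
             stringsAsFactors = FALSE)
}

#' Run the full calibration phase for one or both speeds
#'
#' Convenience wrapper: per speed category, summarizes the grid errors,
#' fits the NB-GEE setting comparison against the empirically best
#' referent, and selects the winning settings.
#'
#' @param records Grid records from [apply_settings_grid()].
#' @param trials Trial table.
#' @param grids Named list of [settings_grid()] per speed category.
#' @param fit_models Fit the NB-GEE comparisons (set `FALSE` for a fast
#'   selection-only pass, e.g. inside replicate studies).
#' @return List of class `calibration_result`: per speed, `errors`,
#'   `irr`, `referent_label`; plus `selected` (data frame, one row per
#'   speed) and `selected_settings` (named list of [detector_settings()]
#'   ready for [count_trials()]).
#' @export
run_calibration <- function(records, trials, grids, fit_models = TRUE) {
  speeds <- names(grids)
  per_speed <- list()
  selected <- list()
  selected_settings <- list()
  for (sp in speeds) {
    errs <- evaluate_grid(records, trials, grids[[sp]], sp)
    cmp <- if (fit_models)
      compare_settings(records, trials, sp) else
      list(irr = NULL, referent_label = NA_character_, fit = NULL)
    sel <- select_settings(errs, grids[[sp]])
    per_speed[[sp]] <- list(errors = errs, irr = cmp$irr,
                            referent_label = cmp$referent_label)
    selected[[sp]] <- sel
    selected_settings[[sp]] <- grids[[sp]][[sel$settings_label]]
  }
  structure(list(per_speed = per_speed,
                 selected = do.call(rbind, selected),
                 selected_settings = selected_settings),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result\n")
  for (sp in names(x$per_speed)) {
    sel <- x$selected[x$selected$speed_category == sp, ]
    cat("  ", sp, ": selected ", sel$settings_label,
        " (mean abs diff ", round(sel$mean_abs_diff, 2), " steps over ",
        x$per_speed[[sp]]$errors$n_obs[1], " obs/setting)\n", sep = "")
  }
  invisible(x)
}
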