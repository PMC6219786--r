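# join counting records (excluding observed) with trials, attach diffs
validation_frame <- function(records, trials) {
  obs <- records[records$method == "observed", c("trial_id", "counted_steps")]
  names(obs)[2] <- "observed_check"
  d <- merge(records[records$method != "observed", , drop = FALSE],
             trials[, c("trial_id", "participant_id", "platform",
                        "speed_category", "distance_m", "observed_steps")],
             by = "trial_id")
  d$abs_diff <- abs_step_difference(d$counted_steps, d$observed_steps)
  d
}

#' Per-cell error summaries for every counting method
#'
#' One row per platform x speed x distance x method with the mean +/- SD
#' (sample SD, n-1) of the absolute step difference and the number of
#' observations — the summary columns of a method-comparison table.
#'
#' @param records Long-format step-count records (from [count_trials()]);
#'   must contain at least two methods besides `observed`.
#' @param trials Trial-metadata data frame.
#' @return Data frame `platform`, `speed_category`, `distance_m`,
#'   `method`, `n_obs`, `mean_abs_diff`, `sd_abs_diff`.
#' @export
summarize_cells <- function(records, trials) {
  meths <- setdiff(unique(records$method), "observed")
  if (length(meths) < 2)
    warning("fewer than 2 counting methods besides `observed`; ",
            "summaries computed but no comparison is possible")
  d <- validation_frame(records, trials)
  agg <- aggregate(abs_diff ~ platform + speed_category + distance_m + method,
                   data = d, FUN = function(x)
                     c(n = length(x), mean = mean(x),
                       sd = if (length(x) > 1) sd(x) else 0))
  out <- data.frame(agg[, c("platform", "speed_category", "distance_m",
                            "method")],
                    n_obs = as.integer(agg$abs_diff[, "n"]),
                    mean_abs_diff = agg$abs_diff[, "mean"],
                    sd_abs_diff = agg$abs_diff[, "sd"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$platform, out$speed_category, out$distance_m,
                   out$method), ]
  rownames(out) <- NULL
  # flag cells missing a method
  cells <- unique(out[, c("platform", "speed_category", "distance_m")])
  for (i in seq_len(nrow(cells))) {
    have <- out$method[out$platform == cells$platform[i] &
                       out$speed_category == cells$speed_category[i] &
                       out$distance_m == cells$distance_m[i]]
    miss <- setdiff(meths, have)
    if (length(miss))
      warning("cell ", cells$platform[i], "/", cells$speed_category[i], "/",
              cells$distance_m[i], "m is missing method(s): ",
              paste(miss, collapse = ", "))
  }
  out
}

#' Method contrast within one platform x speed x distance cell
#'
#' Fits the cell's NB-GEE model: absolute step difference on the counting
#' method indicator (referent `native_baseline`, so the IRR is shake
#' relative to the baseline and IRR < 1 means the shake detector is more
#' accurate), clustered on participant with an exchangeable working
#' correlation and robust SEs.
#'
#' @param records,trials As for [summarize_cells()].
#' @param platform,speed_category,distance Cell coordinates.
#' @param methods Length-2 character: referent first.
#' @return One-row data frame of class `cell_comparison`: cell
#'   coordinates, per-method n/mean/SD, `irr` (with `ci_lower`,
#'   `ci_upper`, `p_value`) and `note` (flags degenerate cells instead of
#'   silently returning NA).
#' @export
compare_methods_cell <- function(records, trials, platform, speed_category,
                                 distance,
                                 methods = c("native_baseline", "shake")) {
  d <- validation_frame(records, trials)
  d <- d[d$platform == platform & d$speed_category == speed_category &
           d$distance_m == distance & d$method %in% methods, , drop = FALSE]
  if (nrow(d) == 0)
    stop("empty cell ", platform, "/", speed_category, "/", distance, "m")
  have <- unique(d$method)
  if (!all(methods %in% have))
    stop("cell ", platform, "/", speed_category, "/", distance,
         "m lacks method(s): ", paste(setdiff(methods, have), collapse = ", "))
  if (length(unique(d$participant_id)) < 2)
    stop("at least 2 participant clusters are required")

  stat <- lapply(methods, function(mm) {
    x <- d$abs_diff[d$method == mm]
    c(n = length(x), mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
  })
  names(stat) <- methods

  note <- ""
  irr <- ci_l <- ci_u <- pval <- NA_real_
  if (all(d$abs_diff == 0)) {
    note <- "degenerate cell: all differences zero - no model fitted"
  } else if (any(vapply(methods, function(mm)
      all(d$abs_diff[d$method == mm] == 0), TRUE))) {
    note <- "one method has all-zero differences - log-linear contrast degenerate"
  } else {
    d$method <- relevel(factor(d$method), methods[1])
    fit <- nbgee(abs_diff ~ method, d, id = d$participant_id)
    if (!fit$converged) note <- "model did not converge"
    else if (fit$family_used == "poisson")
      note <- "no overdispersion - Poisson GEE fallback"
    it <- irr_table(fit)
    row <- it[it$term == paste0("method", methods[2]), ]
    irr <- row$irr; ci_l <- row$ci_lower; ci_u <- row$ci_upper
    pval <- row$p_value
  }
  out <- data.frame(
    platform = platform, speed_category = speed_category,
    distance_m = distance,
    n_ref = as.integer(stat[[1]]["n"]), mean_ref = stat[[1]]["mean"],
    sd_ref = stat[[1]]["sd"],
    n_cmp = as.integer(stat[[2]]["n"]), mean_cmp = stat[[2]]["mean"],
    sd_cmp = stat[[2]]["sd"],
    method_ref = methods[1], method_cmp = methods[2],
    irr = irr, ci_lower = ci_l, ci_upper = ci_u, p_value = pval,
    note = note, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cell_comparison", "data.frame")
  out
}

#' Run the full validation analysis
#'
#' Fits one method-contrast model per platform x speed x distance cell
#' present in the trial table (12 models for the full 2 x 2 x 3 design)
#' and assembles the method-comparison report: per-method mean +/- SD
#' absolute step difference, the shake-vs-baseline IRR with CI, the raw
#' p-value with a significance marker at p < 0.05, and a Holm-adjusted
#' p-value column (reported for transparency; the raw p-values are the
#' primary inference, uncorrected across cells).
#'
#' An incomplete factorial produces a partial report: cells that cannot
#' be fitted are kept as rows with an explanatory `note`, never dropped
#' silently.
#'
#' @param records,trials As for [summarize_cells()].
#' @param methods Length-2 character: referent first.
#' @return Data frame of class `validation_report`, one row per cell.
#' @export
run_validation <- function(records, trials,
                           methods = c("native_baseline", "shake")) {
  cells <- unique(trials[, c("platform", "speed_category", "distance_m")])
  cells <- cells[order(cells$platform, cells$speed_category,
                       cells$distance_m), , drop = FALSE]
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    rows[[i]] <- tryCatch(
      compare_methods_cell(records, trials, cells$platform[i],
                           cells$speed_category[i], cells$distance_m[i],
                           methods = methods),
      error = function(e) {
        data.frame(platform = cells$platform[i],
                   speed_category = cells$speed_category[i],
                   distance_m = cells$distance_m[i],
                   n_ref = NA_integer_, mean_ref = NA_real_, sd_ref = NA_real_,
                   n_cmp = NA_integer_, mean_cmp = NA_real_, sd_cmp = NA_real_,
                   method_ref = methods[1], method_cmp = methods[2],
                   irr = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                   p_value = NA_real_,
                   note = paste("cell not fitted:", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  rep$p_holm <- NA_real_
  ok <- !is.na(rep$p_value)
  rep$p_holm[ok] <- p.adjust(rep$p_value[ok], method = "holm")
  rep$significant <- !is.na(rep$p_value) & rep$p_value < 0.05
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' Render a validation report as a Markdown table
#'
#' One table per platform in the familiar method-comparison layout:
#' rows are distances, columns are speed strata with per-method
#' mean +/- SD absolute step difference and the model p-value.
#' Significant contrasts (p < 0.05) are bolded.
#'
#' @param report A [run_validation()] result.
#' @return Character vector of Markdown lines.
#' @export
validation_markdown <- function(report) {
  fmt <- function(m, s) ifelse(is.na(m), "-",
                               sprintf("%.2f±%.2f", m, s))
  fp <- function(p, sig) ifelse(is.na(p), "-",
    ifelse(sig, sprintf("**%s**", ifelse(p < 0.001, "<0.001",
                                         sprintf("%.3f", p))),
           ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))))
  lines <- character(0)
  for (pf in unique(report$platform)) {
    r <- report[report$platform == pf, , drop = FALSE]
    lines <- c(lines, paste0("### Platform: ", pf), "",
               paste0("| Distance | Slow ", r$method_cmp[1], " | Slow ",
                      r$method_ref[1], " | P | Normal ", r$method_cmp[1],
                      " | Normal ", r$method_ref[1], " | P |"),
               "|---|---|---|---|---|---|---|")
    for (dd in sort(unique(r$distance_m))) {
      sl <- r[r$distance_m == dd & r$speed_category == "slow", ]
      no <- r[r$distance_m == dd & r$speed_category == "normal", ]
      g <- function(x, col) if (nrow(x) == 1) x[[col]] else NA
      lines <- c(lines, sprintf(
        "| %gm | %s | %s | %s | %s | %s | %s |", dd,
        fmt(g(sl, "mean_cmp"), g(sl, "sd_cmp")),
        fmt(g(sl, "mean_ref"), g(sl, "sd_ref")),
        fp(g(sl, "p_value"), isTRUE(g(sl, "significant"))),
        fmt(g(no, "mean_cmp"), g(no, "sd_cmp")),
        fmt(g(no, "mean_ref"), g(no, "sd_ref")),
        fp(g(no, "p_value"), isTRUE(g(no, "significant")))))
    }
    lines <- c(lines, "")
  }
  lines
}
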