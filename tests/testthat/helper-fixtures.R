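# Small cohort fixtures used across test files.

# calibration-style fixture: one distance, both speeds
calibration_cohort <- function(n = 5, platforms = c("ios", "android"),
                               distance = 20, seed = 101) {
  simulate_cohort(cohort_spec(
    n_participants = n, distances = distance, platforms = platforms,
    seed = seed))
}

both_grids <- function() list(slow = default_grid("slow"),
                              normal = default_grid("normal"))

# synthetic long-format records with prescribed absolute errors:
# builds `observed` trials plus one method whose counts are observed + err
records_with_errors <- function(trials, method, err,
                                settings_label = NA_character_) {
  data.frame(trial_id = trials$trial_id, method = method,
             settings_label = settings_label,
             counted_steps = as.integer(trials$observed_steps + err),
             stringsAsFactors = FALSE)
}

# minimal hand-built trial table (no traces), n trials per participant
toy_trials <- function(n_participants = 2, trials_each = 3, observed = 20,
                       platform = "ios", speed_category = "normal",
                       distance = 10) {
  ids <- unlist(lapply(seq_len(n_participants), function(p)
    sprintf("P%d-t%d", p, seq_len(trials_each))))
  data.frame(
    trial_id = ids,
    participant_id = rep(sprintf("P%d", seq_len(n_participants)),
                         each = trials_each),
    platform = platform, distance_m = distance,
    speed_category = speed_category, realized_speed_mps = 1.3,
    trial_index = rep(seq_len(trials_each), n_participants),
    observed_steps = observed, stringsAsFactors = FALSE)
}

# exchangeable negative-binomial-ish counts via gamma frailty shared
# within cluster: marginal mean mu * ratio^(is_treat), overdispersed
sim_clustered_counts <- function(n_clusters, m_per_arm, mu0, ratio,
                                 frailty_shape = 2) {
  id <- rep(seq_len(n_clusters), each = 2 * m_per_arm)
  arm <- rep(rep(c("ref", "alt"), each = m_per_arm), n_clusters)
  u <- rep(rgamma(n_clusters, frailty_shape, frailty_shape),
           each = 2 * m_per_arm)
  mu <- u * mu0 * ifelse(arm == "alt", ratio, 1)
  data.frame(y = rpois(length(mu), mu),
             arm = factor(arm, c("ref", "alt")), id = id)
}
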