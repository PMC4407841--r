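# Shared fixtures and independent oracles.

# Closed-form normal-normal posterior for a single patient's effect with a
# known residual SD and flat prior on the patient level: the likelihood for
# theta collapses to the difference of arm means with variance
# sigma^2 (1/n_p + 1/n_a).
conjugate_posterior <- function(y_placebo, y_active, sigma, prior_mean,
                                prior_sd) {
  that <- mean(y_placebo) - mean(y_active)
  v <- sigma^2 * (1 / length(y_placebo) + 1 / length(y_active))
  post_var <- 1 / (1 / v + 1 / prior_sd^2)
  list(mean = post_var * (that / v + prior_mean / prior_sd^2),
       sd = sqrt(post_var), lik_mean = that, lik_var = v)
}

# Deterministic single-patient series builder (no RNG): explicit outcomes
# per (set, arm).
make_patient_series <- function(outcomes_by_set, patient_id = "P01",
                                subgroup = "chloride") {
  rows <- lapply(seq_along(outcomes_by_set), function(s) {
    os <- outcomes_by_set[[s]]
    do.call(rbind, lapply(names(os), function(arm) {
      data.frame(patient_id = patient_id, subgroup = subgroup, set = s,
                 period = if (arm == "active") 1L else 2L,
                 order = "active_first", arm = arm,
                 day = seq_along(os[[arm]]), outcome = os[[arm]],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("nof1_series", "data.frame")
  out
}

# Small cohort used by several model tests.
quick_cohort <- function(seed, n_patients = 10L, beta0 = 1.75,
                         n_pairs = 2L, obs = 6L, ...) {
  half <- n_patients %/% 2L
  simulate_cohort(
    design_spec(n_patients = n_patients,
                subgroup_split = c(chloride = n_patients - half,
                                   sodium = half),
                obs_per_arm_per_pair = obs),
    cohort_params(beta0 = beta0, ...),
    n_pairs = n_pairs, seed = seed)
}

# Raw per-patient (placebo - active) mean differences.
raw_patient_diffs <- function(series) {
  vapply(split(series, series$patient_id), function(d)
    mean(d$outcome[d$arm == "placebo"]) - mean(d$outcome[d$arm == "active"]),
    0)
}
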