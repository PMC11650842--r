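# Shared fixtures, built in code.

# Arm-level means as printed in the trial's cost/QALY summary tables.
printed_arm_means <- function() {
  arm_means(cost_intervention = 63.03, cost_control = 34.23,
            qaly_intervention = 0.4302, qaly_control = 0.4227)
}

# A small trial configuration for fast generic tests (structure preserved,
# sizes reduced).
small_config <- function(seed = 1L, ...) {
  trial_config(n_clusters = 6L, n_intervention = 60L, n_control = 60L,
               missingness_rate = 0, seed = seed, ...)
}

# Two-group skewed-outcome fixture for GLM closed-form checks.
two_group_fixture <- function(n = 80, seed = 7L, mean_int = 60, mean_ctl = 35) {
  set.seed(seed)
  arm <- rep(c("intervention", "control"), each = n)
  y <- c(rgamma(n, shape = 2, scale = mean_int / 2),
         rgamma(n, shape = 2, scale = mean_ctl / 2))
  data.frame(arm = arm, y = y,
             age = round(runif(2 * n, 35, 68)),
             sex = sample(c("male", "female"), 2 * n, replace = TRUE),
             utility_baseline = runif(2 * n, 0.6, 1))
}

# A minimal analysed frame (arm, covariates, total_cost, qaly) for the
# estimation stage, drawn from the synthetic generator.
analysed_frame <- function(config = small_config(), schedule = price_schedule()) {
  d <- generate_trial(config, schedule = schedule)
  costs <- participant_costs(d, schedule)
  data.frame(
    participant_id = d$participant_id, arm = d$arm, cluster_id = d$cluster_id,
    age = d$age, sex = d$sex, residency = d$residency,
    utility_baseline = d$utility_baseline,
    total_cost = costs$total,
    qaly = participant_qalys(d$utility_baseline, d$utility_followup)
  )
}
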