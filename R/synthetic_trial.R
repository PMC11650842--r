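# Synthetic cluster-RCT generator.
#
# Emulates a 1:1 cluster-randomised trial of a community health-behaviour
# intervention for type 2 diabetes: 30 clusters (15 per arm), 481 adults aged
# 30-70, baseline EQ-5D utilities near the 0.90 ceiling, right-skewed
# (gamma-distributed) 6-month costs per category, and ~7.9% loss to follow-up
# completely at random. Every distributional parameter is carried in the
# TrialConfig so that truth_summary() can state the analytic expectations the
# estimation pipeline should recover.

#' Default per-category cost distribution parameters
#'
#' Means and SDs (USD per patient over 6 months) of the ten cost categories by
#' arm, calibrated to the arm-level summary statistics the analysis targets.
#' Categories with mean 0 in an arm (the intervention-delivery components in
#' the control arm) are emitted as exactly 0.
#'
#' @return Data frame: `category`, `arm`, `mean`, `sd`.
#' @export
default_cost_components <- function() {
  rbind(
    data.frame(
      category = COST_CATEGORIES, arm = "intervention",
      mean = c(4.16, 14.31, 9.35, 2.80, 0.64, 1.62, 12.83, 0.47, 2.53, 14.33),
      sd   = c(6.28,  6.12, 17.73, 30.47, 0.77, 2.18, 24.88, 0.08, 1.37, 7.27)
    ),
    data.frame(
      category = COST_CATEGORIES, arm = "control",
      mean = c(3.85, 13.43, 3.68, 1.45, 0.66, 2.06, 9.11, 0, 0, 0),
      sd   = c(7.05,  5.88, 8.40, 4.68, 0.68, 2.11, 6.55, 0, 0, 0)
    )
  )
}

#' Trial generator configuration
#'
#' Parameters of the synthetic cluster-RCT. Defaults reproduce the study
#' conditions of a 30-cluster, 481-participant, 6-month trial: arm sizes
#' 238/243, age 54.4 (9.4) years truncated to the 30-70 eligibility window,
#' 52.8% male, 64.2% semi-urban, baseline utility mean 0.90 (SD 0.13),
#' follow-up control-arm utility mean 0.7908 with a +0.03 intervention effect
#' on follow-up utility (so that the trapezoidal QALY difference over the
#' 0.5-year horizon is 0.0075), and 7.9% loss to follow-up.
#'
#' Follow-up utility is generated as `u1 = w*u0 + (1-w)*v` where `v` is a
#' scaled Beta on `[utility_floor, 1]`: this keeps utilities inside the tariff
#' range with a ceiling-like right skew and makes all arm-level expectations
#' available in closed form (see [truth_summary()]).
#'
#' @param n_clusters Total clusters (even). Default 30.
#' @param n_intervention,n_control Arm sizes. Defaults 238/243.
#' @param age_mean,age_sd Age distribution (years), truncated to
#'   `[age_range[1], age_range[2]]`.
#' @param age_range Eligibility window, years. Default `c(30, 70)`.
#' @param prop_male,prop_semi_urban Covariate fractions.
#' @param baseline_utility_mean,baseline_utility_sd Baseline EQ-5D utility
#'   moments (both arms).
#' @param followup_control_mean Expected follow-up utility, control arm.
#' @param utility_effect Mean follow-up utility difference (intervention
#'   minus control).
#' @param followup_tracking Weight `w` on baseline utility in the follow-up
#'   mixing model (0 = no tracking, 1 = no change).
#' @param followup_innovation_sd SD of the Beta innovation `v`.
#' @param utility_floor Worst utility representable by the tariff in use.
#' @param cluster_utility_sd SD of an optional additive cluster-level random
#'   effect on follow-up utility (induces within-cluster correlation; no
#'   empirically anchored default exists, so it defaults to 0).
#' @param vas_mean,vas_sd EQ-VAS moments (0-100).
#' @param cost_component_params Data frame as [default_cost_components()].
#' @param missingness_rate Probability of loss to follow-up (MCAR). Default
#'   0.079.
#' @param horizon Trial horizon in years. Default 0.5.
#' @param seed Master seed; all stage substreams derive from it.
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(n_clusters = 30L,
                         n_intervention = 238L, n_control = 243L,
                         age_mean = 54.4, age_sd = 9.4, age_range = c(30, 70),
                         prop_male = 0.528, prop_semi_urban = 0.642,
                         baseline_utility_mean = 0.90, baseline_utility_sd = 0.13,
                         followup_control_mean = 0.7908, utility_effect = 0.03,
                         followup_tracking = 0.4, followup_innovation_sd = 0.30,
                         utility_floor = -0.594,
                         cluster_utility_sd = 0,
                         vas_mean = 70, vas_sd = 15,
                         cost_component_params = default_cost_components(),
                         missingness_rate = 0.079,
                         horizon = 0.5,
                         seed = 1L) {
  cfg <- list(n_clusters = as.integer(n_clusters),
              clusters_per_arm = as.integer(n_clusters) %/% 2L,
              n_intervention = as.integer(n_intervention),
              n_control = as.integer(n_control),
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              prop_male = prop_male, prop_semi_urban = prop_semi_urban,
              baseline_utility_mean = baseline_utility_mean,
              baseline_utility_sd = baseline_utility_sd,
              followup_control_mean = followup_control_mean,
              utility_effect = utility_effect,
              followup_tracking = followup_tracking,
              followup_innovation_sd = followup_innovation_sd,
              utility_floor = utility_floor,
              cluster_utility_sd = cluster_utility_sd,
              vas_mean = vas_mean, vas_sd = vas_sd,
              cost_component_params = cost_component_params,
              missingness_rate = missingness_rate,
              horizon = horizon,
              seed = as.integer(seed))
  validate_trial_config(cfg)
  structure(cfg, class = "trial_config")
}

validate_trial_config <- function(cfg) {
  if (cfg$n_clusters < 2 || cfg$n_clusters %% 2 != 0) {
    stop_domain("n_clusters must be a positive even integer (1:1 cluster randomisation)")
  }
  if (cfg$clusters_per_arm * 2L != cfg$n_clusters) {
    stop_domain("clusters_per_arm x 2 must equal n_clusters")
  }
  if (cfg$n_intervention < 1 || cfg$n_control < 1) {
    stop_domain("arm sizes must be positive")
  }
  assert_fraction(cfg$prop_male, "prop_male")
  assert_fraction(cfg$prop_semi_urban, "prop_semi_urban")
  assert_fraction(cfg$missingness_rate, "missingness_rate")
  assert_positive(cfg$age_sd, "age_sd")
  assert_positive(cfg$horizon, "horizon")
  p <- cfg$cost_component_params
  if (!all(c("category", "arm", "mean", "sd") %in% names(p))) {
    stop_domain("cost_component_params needs columns category, arm, mean, sd")
  }
  pos <- p$mean > 0
  if (any(p$mean < 0) || any(p$sd[pos] <= 0)) {
    stop_domain("gamma cost parameters must be strictly positive where the mean is non-zero")
  }
  w <- cfg$followup_tracking
  if (w < 0 || w >= 1) stop_domain("followup_tracking must be in [0, 1)")
  # the innovation mean implied by the follow-up targets must be feasible
  for (arm_mean in c(cfg$followup_control_mean,
                     cfg$followup_control_mean + cfg$utility_effect)) {
    vmean <- (arm_mean - w * cfg$baseline_utility_mean) / (1 - w)
    beta_shapes(vmean, cfg$followup_innovation_sd, cfg$utility_floor, 1)
  }
  beta_shapes(cfg$baseline_utility_mean, cfg$baseline_utility_sd, cfg$utility_floor, 1)
  invisible(cfg)
}

# Truncated-normal draws by inverse-CDF (exact, vectorised).
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

draw_scaled_beta <- function(n, mean, sd, lo, hi) {
  sh <- beta_shapes(mean, sd, lo, hi)
  lo + (hi - lo) * rbeta(n, sh$shape1, sh$shape2)
}

component_params <- function(cfg, arm) {
  p <- cfg$cost_component_params
  p[p$arm == arm, ]
}

#' Generate a synthetic trial dataset
#'
#' Draws one participant-level dataset under `config`. Deterministic for a
#' fixed `config$seed`: the same configuration always yields bit-identical
#' data.
#'
#' Column dictionary of the returned data frame: `participant_id`,
#' `cluster_id`, `arm` ("intervention"/"control"), `age` (years), `sex`
#' ("male"/"female"), `residency` ("semi-urban"/"rural"), `utility_baseline`,
#' `utility_followup` (NA when lost), `vas_baseline`, `vas_followup`,
#' `lost_to_followup` (logical), resource-use quantities (`consultations`,
#' `screenings`, `medication_spend_nrs`, `inpatient_admissions`,
#' `inpatient_nights`, `transport_trips`, `food_servings`,
#' `work_days_lost_inpatient`, `half_days_outpatient`) and intervention
#' component costs in USD (`int_phone_usd`, `int_peer_usd`,
#' `int_training_usd`; 0 in the control arm). Resource quantities are
#' continuous 6-month aggregates chosen so that pricing them at `schedule`
#' reproduces the drawn category costs exactly; delivery counts behind the
#' intervention components are not emulated (only their cost footprint).
#'
#' @param config A [trial_config()].
#' @param schedule [price_schedule()] used to express the drawn category costs
#'   as resource quantities.
#' @param emit_profiles Also emit discrete EQ-5D-3L profiles by
#'   nearest-profile projection of the generated utilities through `value_set`
#'   (adds columns `eq5d_baseline`/`eq5d_followup` as "21123"-style strings
#'   and replaces the utilities by the projected tariff values).
#' @param value_set Tariff used for profile projection.
#' @return A data frame of participant records (attributes: `config`,
#'   `schedule`).
#' @export
generate_trial <- function(config, schedule = price_schedule(),
                           emit_profiles = FALSE,
                           value_set = synthetic_tto_value_set()) {
  validate_trial_config(config)
  n <- config$n_intervention + config$n_control
  cpa <- config$clusters_per_arm

  # cluster allocation: 1:1 at cluster level, participants spread evenly
  # (round-robin) across the clusters of their arm
  arm <- rep(c("intervention", "control"), c(config$n_intervention, config$n_control))
  cluster_id <- integer(n)
  cluster_id[arm == "intervention"] <- rep_len(seq_len(cpa), config$n_intervention)
  cluster_id[arm == "control"] <- cpa + rep_len(seq_len(cpa), config$n_control)

  set.seed(derive_seed(config$seed, "demographics"))
  age <- rtnorm(n, config$age_mean, config$age_sd, config$age_range[1], config$age_range[2])
  sex <- ifelse(runif(n) < config$prop_male, "male", "female")
  residency <- ifelse(runif(n) < config$prop_semi_urban, "semi-urban", "rural")

  set.seed(derive_seed(config$seed, "utilities"))
  u0 <- draw_scaled_beta(n, config$baseline_utility_mean, config$baseline_utility_sd,
                         config$utility_floor, 1)
  w <- config$followup_tracking
  target <- ifelse(arm == "intervention",
                   config$followup_control_mean + config$utility_effect,
                   config$followup_control_mean)
  v <- numeric(n)
  for (tg in unique(target)) {
    idx <- target == tg
    vmean <- (tg - w * config$baseline_utility_mean) / (1 - w)
    v[idx] <- draw_scaled_beta(sum(idx), vmean, config$followup_innovation_sd,
                               config$utility_floor, 1)
  }
  u1 <- w * u0 + (1 - w) * v
  if (config$cluster_utility_sd > 0) {
    re <- rnorm(config$n_clusters, 0, config$cluster_utility_sd)
    u1 <- pmin(1, pmax(config$utility_floor, u1 + re[cluster_id]))
  }
  vas0 <- rtnorm(n, config$vas_mean, config$vas_sd, 0, 100)
  vas1 <- rtnorm(n, config$vas_mean + 25 * (target - config$baseline_utility_mean),
                 config$vas_sd, 0, 100)

  set.seed(derive_seed(config$seed, "costs"))
  draws <- matrix(0, n, length(COST_CATEGORIES),
                  dimnames = list(NULL, COST_CATEGORIES))
  for (a in c("intervention", "control")) {
    p <- component_params(config, a)
    idx <- arm == a
    for (j in seq_len(nrow(p))) {
      if (p$mean[j] <= 0) next
      gp <- gamma_shape_scale(p$mean[j], p$sd[j])
      draws[idx, p$category[j]] <- rgamma(sum(idx), shape = gp$shape, scale = gp$scale)
    }
  }

  er <- schedule$exchange_rate
  nights <- draws[, "inpatient"] * er / schedule$bed_day
  records <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    cluster_id = sprintf("C%02d", cluster_id),
    arm = arm, age = age, sex = sex, residency = residency,
    utility_baseline = u0, utility_followup = u1,
    vas_baseline = vas0, vas_followup = vas1,
    lost_to_followup = FALSE,
    consultations = draws[, "consultation"] * er / schedule$consultation,
    screenings = draws[, "screening"] * er / schedule$screening,
    medication_spend_nrs = draws[, "medication"] * er,
    inpatient_admissions = as.integer(nights > 0),
    inpatient_nights = nights,
    transport_trips = draws[, "transport"] * er / schedule$transport_trip,
    food_servings = draws[, "food"] * er / schedule$food_serving,
    work_days_lost_inpatient = draws[, "indirect_income_loss"] * er / schedule$minimum_wage,
    half_days_outpatient = 0,
    int_phone_usd = draws[, "intervention_phone"],
    int_peer_usd = draws[, "intervention_peer"],
    int_training_usd = draws[, "intervention_training"]
  )

  if (emit_profiles) {
    lut <- all_profile_utilities(value_set)
    project <- function(u) {
      i <- vapply(u, function(x) which.min(abs(lut$utility - x)), integer(1))
      list(code = apply(lut[i, EQ5D_DIMENSIONS], 1, paste0, collapse = ""),
           utility = lut$utility[i])
    }
    b <- project(records$utility_baseline); f <- project(records$utility_followup)
    records$eq5d_baseline <- b$code
    records$eq5d_followup <- f$code
    records$utility_baseline <- b$utility
    records$utility_followup <- f$utility
  }

  records <- apply_missingness(records, config$missingness_rate,
                               derive_seed(config$seed, "missingness"))
  attr(records, "config") <- config
  attr(records, "schedule") <- schedule
  class(records) <- c("trial_data", "data.frame")
  records
}

#' Blank follow-up outcomes completely at random
#'
#' Flags each record as lost to follow-up independently with probability
#' `rate` and blanks its follow-up EQ-5D utility, profile and VAS.
#'
#' @param records Participant data frame.
#' @param rate Loss-to-follow-up probability in `[0, 1]`.
#' @param seed RNG seed (reproducible).
#' @return The records with `lost_to_followup` set and follow-up fields `NA`.
#' @export
apply_missingness <- function(records, rate, seed = 1L) {
  assert_fraction(rate, "missingness rate")
  set.seed(as.integer(seed))
  lost <- runif(nrow(records)) < rate
  records$lost_to_followup <- lost
  records$utility_followup[lost] <- NA_real_
  records$vas_followup[lost] <- NA_real_
  if (!is.null(records$eq5d_followup)) records$eq5d_followup[lost] <- NA_character_
  records
}

#' Analytic expectations implied by a trial configuration
#'
#' Closed-form arm-level expected values under the generator's distributions:
#' per-category and total costs, follow-up utilities and trapezoidal QALYs,
#' and the implied incremental cost and QALY. These are the oracle against
#' which parameter-recovery of the estimation pipeline is judged.
#'
#' @param config A [trial_config()].
#' @return List with `cost_means` (category x arm), `total_cost`
#'   (per-arm named vector), `delta_cost`, `utility_followup`, `qaly`
#'   (per-arm), and `delta_qaly`.
#' @export
truth_summary <- function(config) {
  validate_trial_config(config)
  p <- config$cost_component_params
  total <- tapply(p$mean, p$arm, sum)
  u0 <- config$baseline_utility_mean
  u1 <- c(intervention = config$followup_control_mean + config$utility_effect,
          control = config$followup_control_mean)
  qaly <- config$horizon * (u0 + u1) / 2
  list(
    cost_means = p,
    total_cost = c(intervention = unname(total["intervention"]),
                   control = unname(total["control"])),
    delta_cost = unname(total["intervention"] - total["control"]),
    utility_baseline = u0,
    utility_followup = u1,
    qaly = qaly,
    delta_qaly = unname(qaly["intervention"] - qaly["control"])
  )
}

#' Read/write participant-level data as CSV
#'
#' Plain-CSV persistence for trial datasets (column dictionary in
#' [generate_trial()]).
#' @param data Participant data frame.
#' @param path CSV path.
#' @export
write_trial_csv <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "cluster_id", "arm", "age", "sex", "residency",
                "utility_baseline", "utility_followup")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_domain("trial CSV lacks required columns: ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(df$arm), c("intervention", "control"))
  if (length(bad)) stop_domain("unknown arm labels: ", paste(bad, collapse = ", "))
  df$lost_to_followup <- df$lost_to_followup %||% is.na(df$utility_followup)
  class(df) <- c("trial_data", "data.frame")
  df
}

#' Read/write a trial configuration as a flat YAML file
#' @param config A [trial_config()].
#' @param path YAML path.
#' @export
write_trial_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$cost_component_params <- as.list(cfg$cost_component_params)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_trial_config
#' @export
read_trial_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$clusters_per_arm <- NULL
  cfg$cost_component_params <- as.data.frame(cfg$cost_component_params)
  do.call(trial_config, cfg)
}
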