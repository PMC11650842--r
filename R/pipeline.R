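# End-to-end orchestration: (load | generate) -> cost -> QALY -> missing-data
# handling -> Park test -> GLM + bootstrap -> Rubin pooling -> ICER/NMB ->
# CE plane / CEAC -> scenario battery -> report bundle.

#' Analysis configuration
#'
#' Assembles everything [run_full_analysis()] needs. Input is either a
#' participant-level dataset (`data`: a data frame or CSV path) or a
#' generator configuration (`generator`); prices and the value set may be
#' objects or CSV paths.
#'
#' @param data Participant-level data frame or CSV path (optional; the
#'   generator is used when absent).
#' @param generator A [trial_config()] used when `data` is absent.
#' @param prices A [price_schedule()] or CSV path.
#' @param value_set An [eq5d_value_set()] or CSV path (used when the data
#'   carry EQ-5D profiles rather than utilities).
#' @param B Total bootstrap replicates (split across imputations). Default
#'   10000.
#' @param m Imputations when follow-up outcomes are missing (>= 2). Default 5.
#' @param threshold [threshold_from_gdp()].
#' @param lambda_grid CEAC grid (default 0 to 3x threshold, 101 points).
#' @param seed Master seed for generation, imputation and bootstrap.
#' @param include_indirect Include indirect (productivity) costs in the
#'   totals (societal-leaning perspective). Default TRUE.
#' @param include_intervention_cost Include intervention delivery costs in
#'   the cost outcome. Default TRUE.
#' @param cost_family GLM family for the cost model (Park test reported
#'   alongside). Default `"gamma"`.
#' @param cost_covariates,qaly_covariates Adjustment sets for the adjusted
#'   analysis.
#' @param resampling_unit `"participant"` or `"cluster"` bootstrap.
#' @param rounding_mode Rounding convention for the scenario table.
#' @param discount_rate Reserved; must be 0 for a sub-year horizon.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(data = NULL, generator = trial_config(),
                            prices = price_schedule(), value_set = NULL,
                            B = 10000, m = 5,
                            threshold = threshold_from_gdp(),
                            lambda_grid = NULL, seed = 1L,
                            include_indirect = TRUE,
                            include_intervention_cost = TRUE,
                            cost_family = "gamma",
                            cost_covariates = c("age", "sex"),
                            qaly_covariates = "utility_baseline",
                            resampling_unit = "participant",
                            rounding_mode = "printed",
                            discount_rate = 0) {
  if (B < 1) stop_domain("B must be >= 1")
  if (m < 2) stop_domain("m must be >= 2")
  if (discount_rate != 0) {
    stop_domain("discounting is not applied over a sub-year horizon; discount_rate must be 0")
  }
  if (is.character(prices)) prices <- read_price_schedule(prices)
  if (is.character(value_set)) value_set <- read_value_set(value_set)
  if (is.character(data)) data <- read_trial_csv(data)
  if (is.null(data) && is.null(generator)) {
    stop_domain("either data or a generator config must be supplied")
  }
  structure(
    list(data = data, generator = generator, prices = prices,
         value_set = value_set, B = as.integer(B), m = as.integer(m),
         threshold = threshold, lambda_grid = lambda_grid,
         seed = as.integer(seed), include_indirect = include_indirect,
         include_intervention_cost = include_intervention_cost,
         cost_family = cost_family, cost_covariates = cost_covariates,
         qaly_covariates = qaly_covariates, resampling_unit = resampling_unit,
         rounding_mode = rounding_mode, discount_rate = discount_rate),
    class = "analysis_config"
  )
}

baseline_table <- function(data) {
  per_arm <- function(a) {
    d <- data[data$arm == a, ]
    data.frame(arm = a, n = nrow(d),
               age_mean = mean(d$age), age_sd = sd(d$age),
               pct_male = 100 * mean(d$sex == "male"),
               pct_semi_urban = 100 * mean(d$residency == "semi-urban"),
               utility_baseline_mean = mean(d$utility_baseline),
               utility_baseline_sd = sd(d$utility_baseline),
               vas_baseline_mean = mean(d$vas_baseline, na.rm = TRUE),
               vas_baseline_sd = sd(d$vas_baseline, na.rm = TRUE),
               lost_to_followup = sum(d$lost_to_followup))
  }
  rbind(per_arm("intervention"), per_arm("control"))
}

# Pool one outcome's bootstrap results across completed datasets: Rubin on the
# per-imputation point estimates (variance from each imputation's draws), and
# stacked draws for percentile intervals / CEAC.
pool_imputed_bootstrap <- function(boots, what = c("delta_cost", "delta_qaly")) {
  out <- lapply(what, function(w) {
    est <- vapply(boots, function(b) b$estimate[[w]], numeric(1))
    vr <- vapply(boots, function(b) var(b$draws[[w]]), numeric(1))
    if (length(boots) == 1) {
      list(estimate = est, rubin = NULL)
    } else {
      list(estimate = mean(est), rubin = rubin_pool(est, vr))
    }
  })
  names(out) <- what
  out
}

#' Run the full within-trial economic evaluation
#'
#' Executes the whole pipeline under one configuration and master seed; an
#' identical configuration and seed always produces an identical bundle.
#' Stages: load or generate the trial data; price resource use into USD cost
#' breakdowns; value utilities and accrue QALYs; blank cost/QALY outcomes of
#' participants lost to follow-up and multiply impute them; run the modified
#' Park test; fit unadjusted and covariate-adjusted identity-link GLMs with
#' nonparametric bootstrap; Rubin-pool across imputations; derive ICER, NMB,
#' plane probabilities and the CEAC; and evaluate the scenario battery
#' (residency sub-groups, exclusion of each intervention component, and
#' +/-10% scaling of costs and effects).
#'
#' @param config An [analysis_config()].
#' @return Object of class `report_bundle`: `baseline_table`, `cost_table`,
#'   `arm_summary`, `cea_table`, `cea_unadjusted`/`cea_adjusted`
#'   ([cea_result()]s), `scenario_table`, `draws`, `ceac`, `park`,
#'   `metadata`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  schedule <- config$prices
  data <- config$data
  if (is.null(data)) {
    gen <- config$generator
    gen$seed <- derive_seed(config$seed, "generate")
    data <- generate_trial(gen, schedule = schedule)
  }
  if (is.null(data$utility_baseline) && !is.null(data$eq5d_baseline)) {
    vs <- config$value_set %||% synthetic_tto_value_set()
    to_profile <- function(code) as.integer(strsplit(code, "")[[1]])
    data$utility_baseline <- vapply(data$eq5d_baseline,
      function(p) utility_from_profile(to_profile(p), vs), numeric(1))
    data$utility_followup <- vapply(data$eq5d_followup,
      function(p) if (is.na(p)) NA_real_ else utility_from_profile(to_profile(p), vs),
      numeric(1))
  }

  costs <- participant_costs(data, schedule, config$include_indirect)
  horizon <- attr(data, "config")$horizon %||% 0.5
  frame <- data.frame(
    participant_id = costs$participant_id,
    arm = data$arm, cluster_id = data$cluster_id,
    age = data$age, sex = data$sex, residency = data$residency,
    utility_baseline = data$utility_baseline,
    total_cost = if (config$include_intervention_cost) costs$total
                 else costs$total - costs$intervention_total,
    qaly = participant_qalys(data$utility_baseline, data$utility_followup, horizon),
    stringsAsFactors = FALSE
  )
  lost <- which(data$lost_to_followup | is.na(data$utility_followup))
  frame$total_cost[lost] <- NA_real_
  frame$qaly[lost] <- NA_real_

  any_missing <- anyNA(frame$total_cost) || anyNA(frame$qaly)
  completed <- if (any_missing) {
    impute_missing(frame, m = config$m, seed = derive_seed(config$seed, "mi"))
  } else {
    list(frame)
  }

  park <- modified_park_test(data = completed[[1]], outcome = "total_cost",
                             covariates = config$cost_covariates)

  run_boots <- function(adjusted) {
    Bj <- ceiling(config$B / length(completed))
    lapply(seq_along(completed), function(j) {
      bootstrap_incremental(
        completed[[j]], B = Bj,
        seed = derive_seed(config$seed, paste0("boot", if (adjusted) "adj" else "un", j)),
        adjusted = adjusted, resampling_unit = config$resampling_unit,
        cost_family = config$cost_family,
        cost_covariates = config$cost_covariates,
        qaly_covariates = config$qaly_covariates
      )
    })
  }
  stack_draws <- function(boots) {
    boot_draws(
      unlist(lapply(boots, function(b) b$draws$delta_cost)),
      unlist(lapply(boots, function(b) b$draws$delta_qaly)),
      seed = config$seed, adjusted = attr(boots[[1]]$draws, "adjusted"),
      resampling_unit = config$resampling_unit
    )
  }
  boots_un <- run_boots(adjusted = FALSE)
  boots_adj <- run_boots(adjusted = TRUE)
  pool_un <- pool_imputed_bootstrap(boots_un)
  pool_adj <- pool_imputed_bootstrap(boots_adj)
  draws_un <- stack_draws(boots_un)
  draws_adj <- stack_draws(boots_adj)

  cea_un <- cea_result(pool_un$delta_cost$estimate, pool_un$delta_qaly$estimate,
                       draws_un, config$threshold)
  cea_adj <- cea_result(pool_adj$delta_cost$estimate, pool_adj$delta_qaly$estimate,
                        draws_adj, config$threshold)

  observed <- frame[!is.na(frame$total_cost) & !is.na(frame$qaly), ]
  obs_costs <- costs[!seq_len(nrow(costs)) %in% lost, , drop = FALSE]
  cost_table <- arm_cost_table(obs_costs, B = min(config$B, 1000),
                               seed = derive_seed(config$seed, "cost_table"))
  arm_summary <- do.call(rbind, lapply(c("intervention", "control"), function(a) {
    d <- observed[observed$arm == a, ]
    data.frame(arm = a, n = nrow(d),
               cost_mean = mean(d$total_cost), cost_sd = sd(d$total_cost),
               qaly_mean = mean(d$qaly), qaly_sd = sd(d$qaly))
  }))

  cea_row <- function(label, res) {
    data.frame(analysis = label,
               delta_cost = res$delta_cost,
               ci_cost_lower = res$ci_cost[1], ci_cost_upper = res$ci_cost[2],
               delta_qaly = res$delta_qaly,
               ci_qaly_lower = res$ci_qaly[1], ci_qaly_upper = res$ci_qaly[2],
               icer = res$icer,
               nmb = res$nmb,
               ci_nmb_lower = res$ci_nmb[1], ci_nmb_upper = res$ci_nmb[2],
               prob_cost_effective = res$prob_cost_effective,
               prob_cost_saving = res$prob_cost_saving,
               cost_effective = !is.na(res$icer) && res$nmb > 0)
  }
  cea_table <- rbind(cea_row("unadjusted", cea_un), cea_row("adjusted", cea_adj))

  base_means <- arm_means_from_data(observed)
  comp_mean <- function(col) mean(obs_costs[[col]][obs_costs$arm == "intervention"])
  cat_means <- function(cats) {
    do.call(rbind, lapply(c("intervention", "control"), function(a) {
      data.frame(category = cats, arm = a,
                 mean = vapply(cats, function(cc) mean(obs_costs[[cc]][obs_costs$arm == a]),
                               numeric(1)))
    }))
  }
  rm_ <- config$rounding_mode
  thr <- config$threshold
  scenario_table <- rbind(
    scenario_from_means(base_means, "base_case", thr, rm_),
    subgroup_analysis(observed, "residency", "semi-urban", thr, rm_),
    subgroup_analysis(observed, "residency", "rural", thr, rm_),
    component_exclusion(base_means, "phone", comp_mean("intervention_phone"), thr, rm_),
    component_exclusion(base_means, "peer", comp_mean("intervention_peer"), thr, rm_),
    component_exclusion(base_means, "training", comp_mean("intervention_training"), thr, rm_),
    scale_scenario(base_means, 1.1, 1.1, thr, rm_, id = "costs_effects_up_10"),
    scale_scenario(base_means, 0.9, 0.9, thr, rm_, id = "costs_effects_down_10"),
    scale_categories_scenario(base_means, cat_means(c("screening", "intervention_training")),
                              1.1, thr, rm_, id = "screening_training_up_10"),
    scale_categories_scenario(base_means, cat_means(c("screening", "intervention_training")),
                              0.9, thr, rm_, id = "screening_training_down_10")
  )

  curve <- ceac(draws_adj, config$lambda_grid, config$threshold)

  bundle <- list(
    baseline_table = baseline_table(data),
    cost_table = cost_table,
    arm_summary = arm_summary,
    cea_table = cea_table,
    cea_unadjusted = cea_un,
    cea_adjusted = cea_adj,
    scenario_table = scenario_table,
    draws = draws_adj,
    draws_unadjusted = draws_un,
    ceac = curve,
    park = park,
    pooling = list(unadjusted = pool_un, adjusted = pool_adj),
    metadata = list(
      seed = config$seed, B = config$B, m = config$m,
      n_imputations_used = length(completed),
      n_participants = nrow(frame), n_lost = length(lost),
      threshold = as_lambda(config$threshold),
      cost_family = config$cost_family,
      park_slope = park$slope, park_family = park$recommended_family,
      include_indirect = config$include_indirect,
      include_intervention_cost = config$include_intervention_cost,
      resampling_unit = config$resampling_unit,
      n_redraws = sum(vapply(c(boots_un, boots_adj), function(b) b$n_redraws, integer(1))),
      package_version = as.character(utils::packageVersion("trialcea"))
    )
  )
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Within-trial economic evaluation report bundle\n")
  cat(sprintf("  participants: %d (%d lost to follow-up)\n",
              x$metadata$n_participants, x$metadata$n_lost))
  cat(sprintf("  bootstrap B = %d, imputations m = %d, seed = %d\n",
              x$metadata$B, x$metadata$n_imputations_used, x$metadata$seed))
  cat(sprintf("  Park slope %.2f -> %s family\n",
              x$metadata$park_slope, x$metadata$park_family))
  cat("\nAdjusted analysis:\n")
  print(x$cea_adjusted)
  invisible(x)
}

#' Write a report bundle to CSV/JSON files
#'
#' Emits `baseline.csv`, `costs.csv`, `arm_summary.csv`, `cea.csv`,
#' `scenarios.csv`, `draws.csv`, `ceac.csv` and `metadata.json` (seeds, B, m
#' and provenance) into `dir`.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) write.csv(df, file.path(dir, name), row.names = FALSE)
  w(bundle$baseline_table, "baseline.csv")
  w(bundle$cost_table, "costs.csv")
  w(bundle$arm_summary, "arm_summary.csv")
  w(bundle$cea_table, "cea.csv")
  w(bundle$scenario_table, "scenarios.csv")
  w(as.data.frame(bundle$draws), "draws.csv")
  w(bundle$ceac, "ceac.csv")
  jsonlite::write_json(bundle$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
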