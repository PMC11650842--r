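test_that("default configuration reproduces the trial structure", {
  d <- generate_trial(trial_config(seed = 11))
  expect_equal(nrow(d), 481)
  expect_equal(sum(d$arm == "intervention"), 238)
  expect_equal(sum(d$arm == "control"), 243)
  expect_equal(length(unique(d$cluster_id)), 30)
  # balanced cluster randomisation, and each cluster maps to exactly one arm
  tab <- table(unique(data.frame(d$cluster_id, d$arm)))
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(unname(colSums(tab > 0)), c(15, 15))
  expect_true(all(d$age >= 30 & d$age <= 70))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_trial(trial_config(seed = 5))
  b <- generate_trial(trial_config(seed = 5))
  expect_identical(a, b)
  c <- generate_trial(trial_config(seed = 6))
  expect_false(identical(a, c))
})

test_that("generated utilities and costs respect their supports", {
  cfg <- trial_config(seed = 2)
  d <- generate_trial(cfg)
  expect_true(all(d$utility_baseline >= cfg$utility_floor & d$utility_baseline <= 1))
  u1 <- d$utility_followup[!is.na(d$utility_followup)]
  expect_true(all(u1 >= cfg$utility_floor & u1 <= 1))
  costs <- participant_costs(d, price_schedule())
  categories <- c("consultation", "screening", "medication", "inpatient",
                  "transport", "food", "indirect_income_loss",
                  "intervention_phone", "intervention_peer", "intervention_training")
  expect_true(all(as.matrix(costs[, categories]) >= 0))
  expect_true(all(costs$intervention_total[costs$arm == "control"] == 0))
})

test_that("lost records carry no follow-up outcomes and rates behave at the extremes", {
  d0 <- generate_trial(trial_config(seed = 3, missingness_rate = 0))
  expect_equal(sum(d0$lost_to_followup), 0)
  expect_false(anyNA(d0$utility_followup))

  d1 <- apply_missingness(d0, rate = 1, seed = 9)
  expect_true(all(d1$lost_to_followup))
  expect_true(all(is.na(d1$utility_followup)))
  expect_true(all(is.na(d1$vas_followup)))

  same <- apply_missingness(d0, rate = 0, seed = 9)
  expect_identical(same$utility_followup, d0$utility_followup)

  dm <- generate_trial(trial_config(seed = 4))
  expect_true(all(is.na(dm$utility_followup[dm$lost_to_followup])))
  expect_false(anyNA(dm$utility_followup[!dm$lost_to_followup]))

  expect_error(apply_missingness(d0, rate = 1.2), "\\[0, 1\\]")
})

test_that("loss to follow-up matches its binomial expectation over replicates", {
  d <- generate_trial(trial_config(seed = 1, missingness_rate = 0))
  counts <- vapply(1:1000, function(s) {
    sum(apply_missingness(d, 0.079, seed = s)$lost_to_followup)
  }, numeric(1))
  # E[count] = 0.079 * 481 = 38.0; MC error of the mean over 1000 reps ~ 0.19
  expect_equal(mean(counts), 0.079 * 481, tolerance = 0.03)
})

test_that("gamma cost draws reproduce the configured moments at scale", {
  cfg <- trial_config(n_intervention = 6000L, n_control = 6000L,
                      missingness_rate = 0, seed = 8)
  d <- generate_trial(cfg)
  costs <- participant_costs(d, price_schedule())
  p <- cfg$cost_component_params
  n <- 6000
  for (a in c("intervention", "control")) {
    pa <- p[p$arm == a & p$mean > 0, ]
    for (j in seq_len(nrow(pa))) {
      x <- costs[costs$arm == a, pa$category[j]]
      shape <- pa$mean[j]^2 / pa$sd[j]^2
      # Monte-Carlo tolerances (5 relative SEs): mean SE = cv/sqrt(n);
      # sd SE ~ 0.5*sqrt((excess kurtosis + 2)/n), kurtosis 6/shape for a gamma
      tol_mean <- 5 * (pa$sd[j] / pa$mean[j]) / sqrt(n)
      tol_sd <- 5 * 0.5 * sqrt((6 / shape + 2) / n)
      expect_equal(mean(x), pa$mean[j], tolerance = tol_mean,
                   label = paste("mean", a, pa$category[j]))
      expect_equal(sd(x), pa$sd[j], tolerance = tol_sd,
                   label = paste("sd", a, pa$category[j]))
    }
  }
})

test_that("truth_summary returns the analytic expectations of the configuration", {
  ts <- truth_summary(trial_config())
  # printed arm totals sum the per-category means; printed tables round each
  # cell, so cross-sums agree only to +/-0.03
  expect_equal(unname(ts$total_cost["intervention"]), 63.03, tolerance = 0.02)
  expect_equal(unname(ts$total_cost["control"]), 34.23, tolerance = 0.02)
  expect_equal(ts$delta_cost, 28.80, tolerance = 1e-10)
  expect_equal(ts$delta_qaly, 0.0075, tolerance = 1e-10)
  expect_equal(unname(ts$qaly["intervention"]), 0.4302, tolerance = 1e-10)

  # linearity: the cost difference is the sum of per-category differences
  p <- ts$cost_means
  per_cat <- sum(p$mean[p$arm == "intervention"]) - sum(p$mean[p$arm == "control"])
  expect_identical(ts$delta_cost, unname(per_cat))

  ts0 <- truth_summary(trial_config(utility_effect = 0))
  expect_equal(ts0$delta_qaly, 0)
})

test_that("invalid configurations are rejected", {
  expect_error(trial_config(n_clusters = 31), "even")
  expect_error(trial_config(n_intervention = 0), "positive")
  expect_error(trial_config(prop_male = 1.4), "\\[0, 1\\]")
  expect_error(trial_config(missingness_rate = -0.1), "\\[0, 1\\]")
  bad <- default_cost_components()
  bad$sd[1] <- 0
  expect_error(trial_config(cost_component_params = bad), "strictly positive")
})

test_that("profile emission projects utilities through the tariff", {
  vs <- synthetic_tto_value_set()
  d <- generate_trial(small_config(seed = 13), emit_profiles = TRUE, value_set = vs)
  expect_true(all(grepl("^[123]{5}$", d$eq5d_baseline)))
  # emitted utilities equal the tariff value of the emitted profile
  u <- vapply(seq_len(nrow(d)), function(i) {
    utility_from_profile(as.integer(strsplit(d$eq5d_baseline[i], "")[[1]]), vs)
  }, numeric(1))
  expect_equal(d$utility_baseline, u)
})

test_that("trial data and configuration survive CSV/YAML round trips", {
  d <- generate_trial(small_config(seed = 21))
  f <- tempfile(fileext = ".csv")
  write_trial_csv(d, f)
  d2 <- read_trial_csv(f)
  expect_equal(d2$utility_baseline, d$utility_baseline, tolerance = 1e-12)
  expect_identical(d2$arm, d$arm)

  cfg <- trial_config(seed = 77, missingness_rate = 0.1)
  fy <- tempfile(fileext = ".yaml")
  write_trial_config(cfg, fy)
  cfg2 <- read_trial_config(fy)
  expect_identical(generate_trial(cfg2), generate_trial(cfg))
})
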