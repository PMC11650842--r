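test_that("unadjusted identity-link beta1 equals the raw arm-mean difference for every family", {
  d <- two_group_fixture(n = 120, seed = 3)
  truth <- mean(d$y[d$arm == "intervention"]) - mean(d$y[d$arm == "control"])
  for (fam in c("gaussian", "poisson", "gamma", "inverse_gaussian")) {
    fit <- fit_glm_identity(d, "y", covariates = character(), family = fam)
    expect_equal(fit$beta1, truth, tolerance = 1e-8, label = fam)
  }
})

test_that("gaussian-identity GLM matches the normal-equations oracle coefficient-wise", {
  d <- two_group_fixture(n = 90, seed = 11)
  fit <- fit_glm_identity(d, "y", covariates = c("age", "sex"), family = "gaussian")
  X <- cbind(1, as.numeric(d$arm == "intervention"), d$age,
             as.numeric(factor(d$sex))[drop = TRUE] - 1)
  # independent oracle: solve the normal equations directly
  beta_ols <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(fit$coefficients), c(beta_ols), tolerance = 1e-8)
})

test_that("degenerate outcomes and designs are handled explicitly", {
  d <- two_group_fixture(n = 40, seed = 5)
  d$y <- 7.5
  fit <- fit_glm_identity(d, "y", family = "gaussian")
  expect_equal(unname(fit$coefficients[1]), 7.5)
  expect_equal(fit$beta1, 0)

  # zero costs under a gamma family: lifted by the documented offset
  d2 <- two_group_fixture(n = 40, seed = 6)
  d2$y[1:3] <- 0
  fit2 <- fit_glm_identity(d2, "y", family = "gamma")
  expect_gt(fit2$zero_offset, 0)
  truth <- mean(d2$y[d2$arm == "intervention"]) - mean(d2$y[d2$arm == "control"])
  expect_equal(fit2$beta1, truth, tolerance = 1e-6)

  d3 <- two_group_fixture(n = 30, seed = 7)
  d3$dup <- as.numeric(d3$arm == "intervention")
  expect_error(fit_glm_identity(d3, "y", covariates = "dup"), "rank deficient")
  expect_error(fit_glm_identity(d3, "nope"), "not found")
})

test_that("the modified Park test recovers the mean-variance power law", {
  set.seed(101)
  n <- 5000
  x <- runif(n, 0.5, 3)
  arm <- sample(c("intervention", "control"), n, replace = TRUE)
  mu <- 1 + x + 0.3 * (arm == "intervention")
  gamma_like <- data.frame(arm = arm, x = x,
                           y = rgamma(n, shape = 4, scale = mu / 4))
  pt_gamma <- modified_park_test(data = gamma_like, outcome = "y", covariates = "x")
  expect_equal(pt_gamma$slope, 2, tolerance = 0.15)
  expect_identical(pt_gamma$recommended_family, "gamma")

  homo <- data.frame(arm = arm, x = x, y = mu + rnorm(n, 0, 0.8))
  pt_homo <- modified_park_test(data = homo, outcome = "y", covariates = "x")
  expect_lt(abs(pt_homo$slope), 0.15)
  expect_identical(pt_homo$recommended_family, "gaussian")
})

test_that("Park slope ties and extremes map to the declared families", {
  # fabricate fits whose log(residual^2) ~ log(fitted) slope is exact
  fake_fit <- function(slope) {
    fitted <- exp(seq(0.1, 2, length.out = 50))
    structure(list(fitted = fitted, residuals = fitted^(slope / 2)),
              class = "glm_fit")
  }
  expect_identical(modified_park_test(fake_fit(1.5))$recommended_family, "poisson")
  expect_identical(modified_park_test(fake_fit(2.5))$recommended_family, "gamma")
  expect_identical(modified_park_test(fake_fit(-1))$recommended_family, "gaussian")
  expect_identical(modified_park_test(fake_fit(9))$recommended_family, "inverse_gaussian")
  expect_equal(modified_park_test(fake_fit(1.5))$slope, 1.5, tolerance = 1e-10)
})

test_that("bootstrap bookkeeping: sizes, reproducibility, degenerate data", {
  d <- analysed_frame(small_config(seed = 41))
  b2 <- bootstrap_incremental(d, B = 2, seed = 9, adjusted = FALSE)
  expect_equal(nrow(b2$draws), 2)
  b2bis <- bootstrap_incremental(d, B = 2, seed = 9, adjusted = FALSE)
  expect_identical(as.data.frame(b2$draws), as.data.frame(b2bis$draws))

  # identical participants within arm: every resample is the same dataset
  dd <- d
  dd$total_cost <- ifelse(dd$arm == "intervention", 60, 35)
  dd$qaly <- ifelse(dd$arm == "intervention", 0.44, 0.42)
  b0 <- bootstrap_incremental(dd, B = 25, seed = 1, adjusted = FALSE)
  expect_true(all(b0$draws$delta_cost == 25))
  expect_equal(diff(b0$estimate$ci_cost), 0)

  # percentile bounds are order statistics of the draws
  b <- bootstrap_incremental(d, B = 199, seed = 2, adjusted = FALSE)
  expect_true(all(b$estimate$ci_cost %in% b$draws$delta_cost))
  expect_true(all(b$estimate$ci_qaly %in% b$draws$delta_qaly))
})

test_that("bootstrap distribution is centred at zero under an identical-arms null", {
  cfg <- small_config(seed = 51, utility_effect = 0)
  p <- cfg$cost_component_params
  p[p$arm == "control", c("mean", "sd")] <- p[p$arm == "intervention", c("mean", "sd")]
  d <- analysed_frame(trial_config(n_clusters = 6, n_intervention = 150, n_control = 150,
                                   missingness_rate = 0, utility_effect = 0,
                                   cost_component_params = p, seed = 52))
  # recentre: subtract the observed (finite-sample) mean difference so the
  # only question is whether resampling adds bias
  b <- bootstrap_incremental(d, B = 400, seed = 3, adjusted = FALSE)
  centred <- b$draws$delta_cost - b$estimate$delta_cost
  expect_lt(abs(mean(centred)), 3 * sd(centred) / sqrt(length(centred)) + 1e-9)
})

test_that("adjusted bootstrap refits both models per replicate", {
  d <- analysed_frame(small_config(seed = 61))
  b <- bootstrap_incremental(d, B = 30, seed = 4, adjusted = TRUE,
                             cost_family = "gamma")
  expect_equal(nrow(b$draws), 30)
  expect_true(attr(b$draws, "adjusted"))
  # adjusted and unadjusted point estimates differ once covariates matter
  bu <- bootstrap_incremental(d, B = 1, seed = 4, adjusted = FALSE)
  expect_false(isTRUE(all.equal(b$estimate$delta_qaly, bu$estimate$delta_qaly)))
  # cluster bootstrap runs and keeps both arms
  bc <- bootstrap_incremental(d, B = 5, seed = 5, adjusted = FALSE,
                              resampling_unit = "cluster")
  expect_equal(nrow(bc$draws), 5)
})

test_that("multiple imputation completes follow-up outcomes with between-imputation variation", {
  cfg <- trial_config(n_clusters = 6, n_intervention = 80, n_control = 80,
                      missingness_rate = 0.15, seed = 71)
  sched <- price_schedule()
  d <- generate_trial(cfg, schedule = sched)
  costs <- participant_costs(d, sched)
  frame <- data.frame(arm = d$arm, age = d$age, sex = d$sex,
                      residency = d$residency,
                      utility_baseline = d$utility_baseline,
                      total_cost = costs$total,
                      qaly = participant_qalys(d$utility_baseline, d$utility_followup))
  frame$total_cost[d$lost_to_followup] <- NA
  frame$qaly[d$lost_to_followup] <- NA
  expect_gt(sum(is.na(frame$qaly)), 0)

  imp <- impute_missing(frame, m = 5, seed = 8)
  expect_length(imp, 5)
  for (ds in imp) expect_false(anyNA(ds$qaly) || anyNA(ds$total_cost))
  mis <- which(is.na(frame$qaly))
  across <- sapply(imp, function(ds) ds$qaly[mis[1]])
  expect_gt(var(across), 0)
  # observed values are never touched
  obs <- which(!is.na(frame$qaly))
  expect_identical(imp[[3]]$qaly[obs], frame$qaly[obs])
  # imputed costs respect the outcome's support
  expect_true(all(sapply(imp, function(ds) all(ds$total_cost >= 0))))

  complete <- frame[!is.na(frame$qaly), ]
  imp2 <- impute_missing(complete, m = 3, seed = 8)
  expect_identical(imp2[[1]], complete)
  expect_identical(imp2[[3]], complete)

  bad <- frame; bad$age[2] <- NA
  expect_error(impute_missing(bad, m = 5, seed = 1), "age")
  expect_error(impute_missing(frame, m = 1), ">= 2")
})

test_that("Rubin's rules pool estimates and variances", {
  r <- rubin_pool(c(1, 3), c(1, 1))
  expect_equal(r$estimate, 2)
  expect_equal(r$within, 1)
  expect_equal(r$between, 2)
  expect_equal(r$total_variance, 1 + 1.5 * 2)  # W + (1 + 1/m) B = 4
  expect_true(r$ci[1] < 2 && r$ci[2] > 2)

  # no between-imputation variance: total reduces to W, normal reference
  r0 <- rubin_pool(c(2, 2, 2), c(0.5, 0.5, 0.5))
  expect_equal(r0$total_variance, 0.5)
  expect_identical(r0$df, Inf)

  # homogeneity: scaling estimates by k scales the pool by k and variance by k^2
  k <- 3.7
  rk <- rubin_pool(k * c(1, 3), k^2 * c(1, 1))
  expect_equal(rk$estimate, k * r$estimate)
  expect_equal(rk$total_variance, k^2 * r$total_variance)

  # total variance never below the mean within-imputation variance
  set.seed(9)
  for (i in 1:20) {
    est <- rnorm(5); v <- runif(5)
    rr <- rubin_pool(est, v)
    expect_gte(rr$total_variance, rr$within)
  }
  expect_error(rubin_pool(1, 1), "m >= 2")
  expect_error(rubin_pool(c(1, 2), c(-1, 1)), "non-negative")
})
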