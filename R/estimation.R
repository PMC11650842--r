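# Estimation of incremental costs and QALYs.
#
# The analysis model is an identity-link GLM
#     y = b0 + b1 * treat + b2 * x1 + ...
# where treat is the arm dummy (1 = intervention) and b1 is the adjusted
# incremental cost or QALY. Costs are right-skewed, so the variance family is
# chosen with the modified Park test (slope of log squared residuals on log
# fitted values: 0 gaussian, 1 poisson, 2 gamma, 3 inverse gaussian).
# Uncertainty comes from a nonparametric bootstrap (resampling participants
# within arm, or whole clusters), and loss to follow-up is handled by
# regression-based multiple imputation pooled with Rubin's rules.

GLM_FAMILIES <- c("gaussian", "poisson", "gamma", "inverse_gaussian")

identity_family <- function(family) {
  switch(match.arg(family, GLM_FAMILIES),
         gaussian = gaussian(link = "identity"),
         poisson = poisson(link = "identity"),
         gamma = Gamma(link = "identity"),
         inverse_gaussian = inverse.gaussian(link = "identity"))
}

# Design matrix: intercept, treatment dummy, then covariates (factors expanded).
build_design <- function(data, treatment = "arm", covariates = character()) {
  treat <- as.numeric(data[[treatment]] == "intervention")
  X <- cbind(`(Intercept)` = 1, treatment = treat)
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.null(v)) stop_domain("covariate not found in data: ", cv)
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      mm <- model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(v)[-1])
      X <- cbind(X, mm)
    } else {
      X <- cbind(X, setNames(data.frame(v), cv))
    }
  }
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop_domain("design matrix is rank deficient")
  X
}

#' Fit an identity-link GLM for costs or QALYs
#'
#' Iteratively reweighted least squares via [stats::glm.fit()], with starting
#' values from the ordinary least-squares fit. For the gamma and inverse
#' Gaussian families (support excludes 0), non-positive outcomes are lifted by
#' a small offset: the smallest observed positive outcome times 1e-3 is added
#' to every observation, which leaves the treatment contrast unchanged under
#' the identity link and is recorded in the fit (`zero_offset`).
#'
#' @param data Data frame with the outcome, an `arm` column and any
#'   covariates.
#' @param outcome Name of the outcome column (total cost in USD, or QALYs).
#' @param covariates Covariate names to adjust for (e.g. `c("age", "sex")` for
#'   costs, `"utility_baseline"` for QALYs). Character covariates are expanded
#'   to dummies.
#' @param family One of `"gaussian"`, `"poisson"`, `"gamma"`,
#'   `"inverse_gaussian"`; the link is always identity.
#' @param treatment Name of the arm column (levels "intervention"/"control").
#' @return Object of class `glm_fit`: `coefficients`, `beta1` (the adjusted
#'   incremental effect of treatment), `fitted`, `residuals`, `converged`,
#'   `iterations`, `family`, `zero_offset`.
#' @export
fit_glm_identity <- function(data, outcome, covariates = character(),
                             family = "gaussian", treatment = "arm") {
  y <- data[[outcome]]
  if (is.null(y)) stop_domain("outcome column not found: ", outcome)
  if (any(is.na(y))) stop_domain("outcome contains missing values; impute first")
  X <- build_design(data, treatment, covariates)
  fam_name <- match.arg(family, GLM_FAMILIES)
  zero_offset <- 0
  if (fam_name %in% c("gamma", "inverse_gaussian") && any(y <= 0)) {
    pos <- y[y > 0]
    if (!length(pos)) stop_domain("all outcomes non-positive; gamma-type family unusable")
    zero_offset <- min(pos) * 1e-3
    y <- y + zero_offset
  }
  start <- qr.solve(X, y)
  fit <- suppressWarnings(
    glm.fit(X, y, family = identity_family(fam_name), start = start,
            control = list(maxit = 100))
  )
  if (!fit$converged) {
    stop("GLM (", fam_name, ", identity) did not converge after 100 iterations; ",
         "deviance = ", format(fit$deviance), call. = FALSE)
  }
  structure(
    list(coefficients = fit$coefficients,
         beta1 = unname(fit$coefficients["treatment"]),
         fitted = fit$fitted.values,
         residuals = y - fit$fitted.values,
         converged = fit$converged,
         iterations = fit$iter,
         family = fam_name,
         zero_offset = zero_offset,
         n = length(y)),
    class = "glm_fit"
  )
}

#' Modified Park test for the GLM variance family
#'
#' Regresses the log squared residuals of a provisional fit on the log fitted
#' values; the slope estimates the power in `Var(y) ~ mean^slope`. The slope
#' is mapped to a family by nearest integer (ties broken toward the lower
#' index): 0 gaussian, 1 poisson, 2 gamma, 3 inverse gaussian.
#'
#' @param fit A `glm_fit` (typically gaussian-identity) providing residuals
#'   and fitted values; alternatively supply `data`/`outcome`/`covariates` to
#'   fit one.
#' @inheritParams fit_glm_identity
#' @return Object of class `park_test`: `slope`, `se`, `recommended_family`,
#'   `n_excluded` (observations dropped for non-positive fitted values).
#' @export
modified_park_test <- function(fit = NULL, data = NULL, outcome = NULL,
                               covariates = character()) {
  if (is.null(fit)) {
    fit <- fit_glm_identity(data, outcome, covariates, family = "gaussian")
  }
  keep <- fit$fitted > 0 & fit$residuals != 0
  n_excluded <- sum(fit$fitted <= 0)
  if (!any(keep)) stop("no usable observations for the Park test (all fitted values non-positive)",
                       call. = FALSE)
  lx <- log(fit$fitted[keep])
  ly <- log(fit$residuals[keep]^2)
  pf <- lm.fit(cbind(1, lx), ly)
  slope <- unname(pf$coefficients[2])
  dfres <- length(ly) - 2
  s2 <- sum(pf$residuals^2) / dfres
  se <- sqrt(s2 / sum((lx - mean(lx))^2))
  idx <- min(3, max(0, ceiling(slope - 0.5)))  # x.5 ties go to the lower family
  structure(
    list(slope = slope, se = se,
         recommended_family = GLM_FAMILIES[idx + 1],
         n_excluded = n_excluded, n_used = sum(keep)),
    class = "park_test"
  )
}

# One bootstrap resample of row indices: with replacement within arm
# (preserving arm sizes) or whole clusters within arm.
resample_indices <- function(arm, cluster = NULL, unit = "participant") {
  idx_i <- which(arm == "intervention")
  idx_c <- which(arm == "control")
  if (unit == "participant") {
    c(sample(idx_i, length(idx_i), replace = TRUE),
      sample(idx_c, length(idx_c), replace = TRUE))
  } else {
    pick <- function(idx) {
      cl <- unique(cluster[idx])
      chosen <- sample(cl, length(cl), replace = TRUE)
      unlist(lapply(chosen, function(cc) idx[cluster[idx] == cc]), use.names = FALSE)
    }
    c(pick(idx_i), pick(idx_c))
  }
}

#' Bootstrap the incremental cost and QALY
#'
#' Each replicate resamples participants with replacement within arm
#' (preserving arm sizes; or whole clusters when `resampling_unit =
#' "cluster"`), refits the cost and QALY models, and stores the pair of
#' treatment coefficients. Point estimates come from the full-sample fits and
#' interval estimates are percentile 2.5/97.5 quantiles of the draws.
#'
#' Unadjusted models use the closed-form identity that the identity-link
#' treatment coefficient of a two-group model equals the raw difference in
#' arm means (valid for every family), which makes large replicate counts
#' cheap. Replicates whose design becomes degenerate (e.g. a single sex after
#' resampling) or whose fit fails are redrawn; a warning is raised when more
#' than 1% of replicates needed redrawing.
#'
#' @param data Data frame with `arm`, cost and QALY outcome columns, and any
#'   covariates.
#' @param B Number of bootstrap replicates (>= 1). Default 10000.
#' @param seed RNG seed.
#' @param adjusted Adjust for covariates? When `FALSE` both models are fitted
#'   without covariates.
#' @param resampling_unit `"participant"` (default) or `"cluster"`.
#' @param cost_outcome,qaly_outcome Outcome column names.
#' @param cost_family GLM family for costs (default `"gamma"`).
#' @param cost_covariates,qaly_covariates Adjustment sets (defaults: age and
#'   sex for costs; baseline utility for QALYs).
#' @return List with `draws` (a [boot_draws()] of B pairs), `estimate` (point
#'   estimates and percentile CIs), `n_redraws`, and the full-sample `fits`.
#' @export
bootstrap_incremental <- function(data, B = 10000, seed = 1L, adjusted = TRUE,
                                  resampling_unit = c("participant", "cluster"),
                                  cost_outcome = "total_cost", qaly_outcome = "qaly",
                                  cost_family = "gamma",
                                  cost_covariates = c("age", "sex"),
                                  qaly_covariates = "utility_baseline") {
  resampling_unit <- match.arg(resampling_unit)
  if (B < 1) stop_domain("B must be >= 1")
  if (!all(c("intervention", "control") %in% data$arm)) {
    stop_domain("both arms must be present")
  }
  if (!adjusted) {
    cost_covariates <- character()
    qaly_covariates <- character()
  }
  fit_cost <- fit_glm_identity(data, cost_outcome, cost_covariates, cost_family)
  fit_qaly <- fit_glm_identity(data, qaly_outcome, qaly_covariates, "gaussian")

  set.seed(as.integer(seed))
  n_redraws <- 0L
  simple <- !length(cost_covariates) && !length(qaly_covariates) &&
    resampling_unit == "participant"
  if (simple) {
    # closed form: b1 = mean(intervention) - mean(control) for any family
    yi_c <- data[[cost_outcome]][data$arm == "intervention"]
    yc_c <- data[[cost_outcome]][data$arm == "control"]
    yi_q <- data[[qaly_outcome]][data$arm == "intervention"]
    yc_q <- data[[qaly_outcome]][data$arm == "control"]
    ni <- length(yi_c); nc <- length(yc_c)
    ii <- matrix(sample.int(ni, ni * B, replace = TRUE), nrow = B)
    ic <- matrix(sample.int(nc, nc * B, replace = TRUE), nrow = B)
    dc <- rowMeans(matrix(yi_c[ii], nrow = B)) - rowMeans(matrix(yc_c[ic], nrow = B))
    dq <- rowMeans(matrix(yi_q[ii], nrow = B)) - rowMeans(matrix(yc_q[ic], nrow = B))
  } else {
    dc <- dq <- numeric(B)
    cl <- data$cluster_id
    for (b in seq_len(B)) {
      repeat {
        idx <- resample_indices(data$arm, cl, resampling_unit)
        rep_fit <- tryCatch({
          d <- data[idx, , drop = FALSE]
          c(fit_glm_identity(d, cost_outcome, cost_covariates, cost_family)$beta1,
            fit_glm_identity(d, qaly_outcome, qaly_covariates, "gaussian")$beta1)
        }, error = function(e) NULL)
        if (!is.null(rep_fit)) break
        n_redraws <- n_redraws + 1L
      }
      dc[b] <- rep_fit[1]; dq[b] <- rep_fit[2]
    }
    if (n_redraws > 0.01 * B) {
      warning(sprintf("%d of %d bootstrap replicates were redrawn (degenerate design or failed fit)",
                      n_redraws, B))
    }
  }
  draws <- boot_draws(dc, dq, seed = seed, adjusted = adjusted,
                      resampling_unit = resampling_unit)
  ci_cost <- percentile_ci(dc)
  ci_qaly <- percentile_ci(dq)
  list(
    draws = draws,
    estimate = list(delta_cost = fit_cost$beta1, ci_cost = ci_cost,
                    delta_qaly = fit_qaly$beta1, ci_qaly = ci_qaly,
                    adjusted = adjusted, B = B, seed = seed),
    n_redraws = n_redraws,
    fits = list(cost = fit_cost, qaly = fit_qaly)
  )
}

#' Multiple imputation of follow-up outcomes
#'
#' Fills missing follow-up outcomes (by default QALYs and total costs of
#' participants lost to follow-up) with draws from a normal-model regression
#' imputation: for each outcome, a linear model on the predictors is fitted to
#' the complete cases, the residual variance and coefficients are drawn from
#' their posterior (scaled inverse chi-squared, then conditional normal), and
#' the missing values are imputed as model predictions plus a residual draw.
#' This propagates parameter uncertainty between imputations, which Rubin's
#' rules require.
#'
#' @param data Data frame; missingness must be confined to `outcomes`.
#' @param m Number of completed datasets (>= 2). Default 5.
#' @param seed RNG seed.
#' @param outcomes Outcome columns to impute.
#' @param predictors Fully observed columns used in the imputation models
#'   (the treatment arm is always included).
#' @param lower_bounds Named list of lower bounds enforced on imputed values
#'   (the normal imputation model is unbounded; costs cannot be negative, so
#'   imputed costs are clamped at 0 by default). QALYs are left unbounded:
#'   worse-than-dead utilities can make them negative.
#' @return A list of `m` completed data frames. When nothing is missing, `m`
#'   identical copies of the input.
#' @export
impute_missing <- function(data, m = 5, seed = 1L,
                           outcomes = c("qaly", "total_cost"),
                           predictors = c("arm", "age", "sex", "residency",
                                          "utility_baseline"),
                           lower_bounds = list(total_cost = 0)) {
  if (m < 2) stop_domain("m must be >= 2")
  predictors <- intersect(predictors, names(data))
  for (p in predictors) {
    if (any(is.na(data[[p]]))) stop_domain("imputation predictor has missing values: ", p)
  }
  outcomes <- intersect(outcomes, names(data))
  X <- build_design(data, covariates = setdiff(predictors, "arm"))
  set.seed(derive_seed(seed, "imputation"))
  lapply(seq_len(m), function(j) {
    completed <- data
    for (oc in outcomes) {
      y <- data[[oc]]
      mis <- is.na(y)
      if (!any(mis)) next
      Xo <- X[!mis, , drop = FALSE]; yo <- y[!mis]
      qx <- qr(Xo)
      betahat <- qr.coef(qx, yo)
      res <- yo - Xo %*% betahat
      df <- length(yo) - ncol(Xo)
      sigma2 <- sum(res^2) / rchisq(1, df)
      R <- qr.R(qx)
      beta <- betahat + backsolve(R, rnorm(ncol(Xo))) * sqrt(sigma2)
      imp <- X[mis, , drop = FALSE] %*% beta + rnorm(sum(mis), 0, sqrt(sigma2))
      if (!is.null(lower_bounds[[oc]])) imp <- pmax(imp, lower_bounds[[oc]])
      completed[[oc]][mis] <- imp
    }
    completed
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled point estimate is the mean of the per-imputation estimates; total
#' variance is `W + (1 + 1/m) * B` with `W` the mean within-imputation
#' variance and `B` the between-imputation variance. The confidence interval
#' uses a t reference with Rubin's degrees of freedom
#' `(m - 1) * (1 + W / ((1 + 1/m) * B))^2` (infinite when `B = 0`).
#'
#' @param estimates Numeric vector of per-imputation point estimates (m >= 2).
#' @param variances Their within-imputation variances (non-negative).
#' @param conf Confidence level.
#' @return List: `estimate`, `within`, `between`, `total_variance`, `df`,
#'   `ci` (length-2).
#' @export
rubin_pool <- function(estimates, variances, conf = 0.95) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m) stop_domain("need m >= 2 estimates with matching variances")
  if (any(variances < 0)) stop_domain("variances must be non-negative")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  total <- W + (1 + 1 / m) * B
  df <- if (B == 0) Inf else (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
  half <- qt(1 - (1 - conf) / 2, df) * sqrt(total)
  list(estimate = qbar, within = W, between = B, total_variance = total,
       df = df, ci = c(qbar - half, qbar + half))
}
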