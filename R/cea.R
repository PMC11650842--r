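#' Willingness-to-pay threshold from GDP per capita
#'
#' Builds the WHO-CHOICE style cost-effectiveness threshold: a multiple
#' (conventionally 3) of national gross domestic product per capita.
#'
#' @param gdp_per_capita GDP per capita in USD. Default 1380 (Nepal, 2023 IMF
#'   estimate).
#' @param multiplier Integer multiple of GDP per capita. Default 3.
#' @return An object of class `cea_threshold` with fields `gdp_per_capita`,
#'   `multiplier` and `lambda` (USD per QALY).
#' @examples
#' threshold_from_gdp(1380, 3)$lambda  # 4140
#' @export
threshold_from_gdp <- function(gdp_per_capita = 1380, multiplier = 3) {
  assert_positive(gdp_per_capita, "gdp_per_capita")
  assert_positive(multiplier, "multiplier")
  structure(
    list(gdp_per_capita = gdp_per_capita, multiplier = multiplier,
         lambda = gdp_per_capita * multiplier),
    class = "cea_threshold"
  )
}

as_lambda <- function(threshold) {
  if (inherits(threshold, "cea_threshold")) threshold$lambda
  else if (is.numeric(threshold) && length(threshold) == 1 && threshold >= 0) threshold
  else stop_domain("threshold must be a cea_threshold or a non-negative number")
}

#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_qaly`, sign preserved. Undefined (returned as `NA` with
#' a warning) when the QALY difference is zero; net monetary benefit remains
#' computable in that case.
#'
#' @param delta_cost Incremental cost (USD, intervention minus control).
#' @param delta_qaly Incremental QALYs.
#' @return USD per QALY gained (vectorised).
#' @examples
#' icer(28.80, 0.0075)  # 3840
#' @export
icer <- function(delta_cost, delta_qaly) {
  out <- delta_cost / delta_qaly
  if (any(delta_qaly == 0)) {
    warning("ICER undefined where delta_qaly = 0; returning NA (NMB still computable)")
    out[delta_qaly == 0] <- NA_real_
  }
  out
}

#' Net monetary benefit
#'
#' `delta_qaly * lambda - delta_cost`. Positive NMB at a threshold means the
#' intervention is cost-effective at that willingness to pay.
#'
#' @inheritParams icer
#' @param threshold A `cea_threshold` or a numeric willingness to pay (USD/QALY).
#' @return NMB in USD (vectorised).
#' @examples
#' nmb(28.80, 0.0075, threshold_from_gdp())  # 2.25
#' @export
nmb <- function(delta_cost, delta_qaly, threshold) {
  delta_qaly * as_lambda(threshold) - delta_cost
}

# Quadrant of the cost-effectiveness plane for one (delta_cost, delta_qaly)
# pair: more effective & cheaper = dominant, less effective & dearer =
# dominated, otherwise a trade-off in the NE or SW quadrant.
cea_quadrant <- function(delta_cost, delta_qaly) {
  ifelse(delta_qaly >= 0 & delta_cost <= 0, "dominant",
    ifelse(delta_qaly < 0 & delta_cost > 0, "dominated",
      ifelse(delta_qaly >= 0, "NE-quadrant trade-off", "SW-quadrant trade-off")))
}

#' Bootstrap draw container
#'
#' Pairs of incremental cost and incremental QALY replicates, the substrate of
#' percentile confidence intervals, the cost-effectiveness plane and the CEAC.
#'
#' @param delta_cost,delta_qaly Numeric vectors of equal length.
#' @param seed,adjusted,resampling_unit Provenance metadata stored as
#'   attributes.
#' @return A `boot_draws` data frame with columns `delta_cost`, `delta_qaly`.
#' @export
boot_draws <- function(delta_cost, delta_qaly, seed = NA_integer_,
                       adjusted = NA, resampling_unit = "participant") {
  if (length(delta_cost) != length(delta_qaly)) {
    stop_domain("delta_cost and delta_qaly must have equal length")
  }
  structure(
    data.frame(delta_cost = delta_cost, delta_qaly = delta_qaly),
    seed = seed, adjusted = adjusted, resampling_unit = resampling_unit,
    class = c("boot_draws", "data.frame")
  )
}

#' Cost-effectiveness plane summary
#'
#' Classifies each bootstrap draw by quadrant and reports the probability of
#' the intervention being cost-effective (NMB strictly positive at the
#' threshold) and cost-saving (negative incremental cost).
#'
#' @param draws A [boot_draws()] object (or data frame with `delta_cost`,
#'   `delta_qaly`).
#' @inheritParams nmb
#' @return A list with `quadrant_proportions` (named, sums to 1),
#'   `prob_cost_effective`, `prob_cost_saving` and `n_draws`.
#' @export
ce_plane_summary <- function(draws, threshold) {
  if (NROW(draws) < 1) stop_domain("at least one draw is required")
  lambda <- as_lambda(threshold)
  q <- cea_quadrant(draws$delta_cost, draws$delta_qaly)
  levels <- c("dominant", "NE-quadrant trade-off", "SW-quadrant trade-off", "dominated")
  props <- table(factor(q, levels = levels)) / length(q)
  list(
    quadrant_proportions = setNames(as.numeric(props), levels),
    prob_cost_effective = mean(draws$delta_qaly * lambda - draws$delta_cost > 0),
    prob_cost_saving = mean(draws$delta_cost < 0),
    n_draws = NROW(draws)
  )
}

#' Cost-effectiveness acceptability curve
#'
#' Probability of positive net monetary benefit as a function of the
#' willingness-to-pay threshold, evaluated over a grid of lambda values.
#' At any grid point the curve equals [ce_plane_summary()]'s
#' `prob_cost_effective` for the same draws exactly.
#'
#' @inheritParams ce_plane_summary
#' @param lambda_grid Ascending non-negative thresholds (USD/QALY). Default:
#'   0 to 3x the threshold in 100 steps.
#' @return Data frame with columns `lambda`, `prob_cost_effective`.
#' @export
ceac <- function(draws, lambda_grid = NULL, threshold = threshold_from_gdp()) {
  if (is.null(lambda_grid)) {
    lambda_grid <- seq(0, 3 * as_lambda(threshold), length.out = 101)
  }
  if (length(lambda_grid) == 0 || is.unsorted(lambda_grid)) {
    stop_domain("lambda_grid must be non-empty and ascending")
  }
  prob <- vapply(
    lambda_grid,
    function(l) mean(draws$delta_qaly * l - draws$delta_cost > 0),
    numeric(1)
  )
  data.frame(lambda = lambda_grid, prob_cost_effective = prob)
}

#' Assemble a full cost-effectiveness result
#'
#' Combines point estimates with bootstrap draws into the decision quantities:
#' ICER, NMB at the threshold, dominance class, percentile intervals and the
#' probabilities of cost-effectiveness and cost saving.
#'
#' The ICER percentile interval is computed on the draw-wise ratio and flagged
#' unstable (`icer_ci_unstable`) when draws straddle `delta_qaly = 0`, in which
#' case the ratio changes sign discontinuously and the interval should be read
#' together with the plane probabilities.
#'
#' @param delta_cost,delta_qaly Point estimates (full-sample fits).
#' @param draws Optional [boot_draws()]; without it only point quantities are
#'   filled.
#' @inheritParams nmb
#' @param conf Confidence level for percentile intervals.
#' @return An object of class `cea_result`.
#' @export
cea_result <- function(delta_cost, delta_qaly, draws = NULL,
                       threshold = threshold_from_gdp(), conf = 0.95) {
  lambda <- as_lambda(threshold)
  point_icer <- if (delta_qaly == 0) NA_real_ else delta_cost / delta_qaly
  res <- list(
    delta_cost = delta_cost,
    delta_qaly = delta_qaly,
    icer = point_icer,
    nmb = delta_qaly * lambda - delta_cost,
    dominance = cea_quadrant(delta_cost, delta_qaly),
    lambda = lambda
  )
  if (!is.null(draws) && NROW(draws) > 0) {
    a <- (1 - conf) / 2
    plane <- ce_plane_summary(draws, lambda)
    nmb_draws <- draws$delta_qaly * lambda - draws$delta_cost
    icer_draws <- draws$delta_cost / draws$delta_qaly
    res$prob_cost_effective <- plane$prob_cost_effective
    res$prob_cost_saving <- plane$prob_cost_saving
    res$quadrant_proportions <- plane$quadrant_proportions
    res$ci_cost <- percentile_ci(draws$delta_cost, conf)
    res$ci_qaly <- percentile_ci(draws$delta_qaly, conf)
    res$ci_nmb <- percentile_ci(nmb_draws, conf)
    res$ci_icer <- percentile_ci(icer_draws[is.finite(icer_draws)], conf)
    res$icer_ci_unstable <- min(draws$delta_qaly) < 0 && max(draws$delta_qaly) > 0
    res$n_draws <- NROW(draws)
  }
  structure(res, class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Within-trial cost-effectiveness result\n")
  cat(sprintf("  Incremental cost : %.2f USD\n", x$delta_cost))
  cat(sprintf("  Incremental QALY : %.4f\n", x$delta_qaly))
  cat(sprintf("  ICER             : %s USD/QALY\n",
              if (is.na(x$icer)) "undefined" else sprintf("%.2f", x$icer)))
  cat(sprintf("  NMB at %.0f    : %.2f USD\n", x$lambda, x$nmb))
  cat(sprintf("  Dominance        : %s\n", x$dominance))
  if (!is.null(x$prob_cost_effective)) {
    cat(sprintf("  P(cost-effective): %.4f   P(cost-saving): %.4f   (B = %d)\n",
                x$prob_cost_effective, x$prob_cost_saving, x$n_draws))
    if (isTRUE(x$icer_ci_unstable)) {
      cat("  Note: draws straddle delta QALY = 0; ICER percentile CI is unstable.\n")
    }
  }
  invisible(x)
}
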