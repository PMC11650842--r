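# Sub-group, component-exclusion and price/effect-scaling scenario analyses.
#
# Scenario transforms operate on arm-level summary means (mean cost in USD
# and mean QALYs per arm), as scenario tables in within-trial evaluations are
# conventionally built. Two rounding conventions are supported:
#   printed   - incremental cost rounded (half-up) to 2 decimals and
#               incremental QALYs to 4 decimals before the ICER division,
#               matching how published scenario tables are assembled;
#   unrounded - fully unrounded arithmetic, under which scaling costs and
#               effects by the same factor leaves the ICER exactly invariant.

#' Arm-level summary means
#'
#' @param cost_intervention,cost_control Mean total cost per patient (USD).
#' @param qaly_intervention,qaly_control Mean QALYs per patient.
#' @return Object of class `arm_means`.
#' @export
arm_means <- function(cost_intervention, cost_control,
                      qaly_intervention, qaly_control) {
  structure(list(cost_intervention = cost_intervention,
                 cost_control = cost_control,
                 qaly_intervention = qaly_intervention,
                 qaly_control = qaly_control),
            class = "arm_means")
}

#' Scenario result from arm-level means
#'
#' Computes incremental cost, incremental QALYs, the ICER and the
#' cost-effectiveness flag at a threshold from arm means, under the chosen
#' rounding convention.
#'
#' @param means An [arm_means()].
#' @param id Scenario identifier.
#' @param threshold [threshold_from_gdp()] or numeric lambda.
#' @param rounding_mode `"printed"` or `"unrounded"` (see module notes).
#' @return One-row data frame: `scenario`, arm means, `delta_cost`,
#'   `delta_qaly`, `icer`, `cost_effective`.
#' @export
scenario_from_means <- function(means, id = "scenario",
                                threshold = threshold_from_gdp(),
                                rounding_mode = c("printed", "unrounded")) {
  rounding_mode <- match.arg(rounding_mode)
  lambda <- as_lambda(threshold)
  dc <- means$cost_intervention - means$cost_control
  dq <- means$qaly_intervention - means$qaly_control
  if (rounding_mode == "printed") {
    dc <- round_half_up(dc, 2)
    dq <- round_half_up(dq, 4)
  }
  ic <- if (dq == 0) NA_real_ else dc / dq
  if (rounding_mode == "printed" && !is.na(ic)) ic <- round_half_up(ic, 2)
  data.frame(scenario = id,
             cost_intervention = means$cost_intervention,
             cost_control = means$cost_control,
             qaly_intervention = means$qaly_intervention,
             qaly_control = means$qaly_control,
             delta_cost = dc, delta_qaly = dq, icer = ic,
             cost_effective = !is.na(ic) && dq > 0 && ic < lambda)
}

#' Arm means of an analysed participant-level frame
#'
#' Mean total cost and QALYs per arm from a frame with `arm`, `total_cost`
#' and `qaly` columns; rows with missing outcomes are dropped.
#' @param data Analysed participant-level data frame.
#' @return An [arm_means()] object.
#' @export
arm_means_from_data <- function(data) {
  ok <- !is.na(data$total_cost) & !is.na(data$qaly)
  d <- data[ok, , drop = FALSE]
  by_arm <- function(col, arm) mean(d[[col]][d$arm == arm])
  arm_means(by_arm("total_cost", "intervention"), by_arm("total_cost", "control"),
            by_arm("qaly", "intervention"), by_arm("qaly", "control"))
}

#' Sub-group analysis
#'
#' Restricts the analysed dataset to one stratum of a grouping variable
#' (e.g. residency = "semi-urban") and recomputes arm means, increments and
#' the ICER within it.
#'
#' @param data Analysed participant-level data frame (columns `arm`,
#'   `total_cost`, `qaly`, and the stratification variable).
#' @param variable Stratification column name.
#' @param level Stratum value to keep.
#' @inheritParams scenario_from_means
#' @return One-row scenario data frame (see [scenario_from_means()]).
#' @export
subgroup_analysis <- function(data, variable, level,
                              threshold = threshold_from_gdp(),
                              rounding_mode = "printed") {
  if (is.null(data[[variable]])) stop_domain("no such variable: ", variable)
  sub <- data[data[[variable]] == level, , drop = FALSE]
  ok <- !is.na(sub$total_cost) & !is.na(sub$qaly)
  sub <- sub[ok, , drop = FALSE]
  if (!all(c("intervention", "control") %in% sub$arm)) {
    stop_domain("stratum ", variable, " = ", level, " lacks one of the arms")
  }
  scenario_from_means(arm_means_from_data(sub),
                      id = paste0(variable, "=", level),
                      threshold = threshold, rounding_mode = rounding_mode)
}

#' Component-exclusion scenario
#'
#' Removes one intervention component's per-patient mean cost (phone calls,
#' peer support, or intensive training) from the intervention arm's mean
#' total cost, leaves QALYs unchanged, and recomputes the ICER.
#'
#' @param means Base-case [arm_means()].
#' @param component Label (`"phone"`, `"peer"`, `"training"`).
#' @param component_cost Per-patient mean cost of the excluded component
#'   (USD); must not exceed the intervention-arm mean.
#' @inheritParams scenario_from_means
#' @return One-row scenario data frame.
#' @export
component_exclusion <- function(means, component, component_cost,
                                threshold = threshold_from_gdp(),
                                rounding_mode = "printed") {
  assert_positive(component_cost, "component_cost", strict = FALSE)
  if (component_cost > means$cost_intervention) {
    stop_domain("component cost exceeds the intervention-arm mean total cost")
  }
  m <- means
  m$cost_intervention <- means$cost_intervention - component_cost
  scenario_from_means(m, id = paste0("exclude_", component),
                      threshold = threshold, rounding_mode = rounding_mode)
}

#' Cost/effect scaling scenario
#'
#' Multiplies arm mean costs by `cost_factor` and arm mean QALYs by
#' `effect_factor` (both arms), then recomputes increments and the ICER. In
#' `"unrounded"` mode, equal factors leave the ICER exactly at its base-case
#' value; `"printed"` mode reproduces the small drift introduced by rounding
#' the increments to reporting precision before the division.
#'
#' @param means Base-case [arm_means()].
#' @param cost_factor,effect_factor Strictly positive multipliers.
#' @inheritParams scenario_from_means
#' @param id Scenario identifier.
#' @return One-row scenario data frame.
#' @export
scale_scenario <- function(means, cost_factor = 1, effect_factor = 1,
                           threshold = threshold_from_gdp(),
                           rounding_mode = c("printed", "unrounded"),
                           id = NULL) {
  assert_positive(cost_factor, "cost_factor")
  assert_positive(effect_factor, "effect_factor")
  m <- arm_means(means$cost_intervention * cost_factor,
                 means$cost_control * cost_factor,
                 means$qaly_intervention * effect_factor,
                 means$qaly_control * effect_factor)
  scenario_from_means(
    m,
    id = id %||% sprintf("scale_cost_%g_effect_%g", cost_factor, effect_factor),
    threshold = threshold, rounding_mode = match.arg(rounding_mode)
  )
}

#' Scale selected cost categories only
#'
#' Variant of the scaling scenario in which only named cost categories (e.g.
#' screening and intensive training) are scaled; arm mean totals are adjusted
#' by the scaled categories' mean contribution per arm.
#'
#' @param means Base-case [arm_means()].
#' @param category_means Data frame `category`, `arm`, `mean` of per-patient
#'   mean costs for the scaled categories.
#' @param factor Multiplier applied to those categories.
#' @inheritParams scale_scenario
#' @return One-row scenario data frame.
#' @export
scale_categories_scenario <- function(means, category_means, factor,
                                      threshold = threshold_from_gdp(),
                                      rounding_mode = "printed", id = NULL) {
  assert_positive(factor, "factor")
  adj <- function(arm) sum(category_means$mean[category_means$arm == arm]) * (factor - 1)
  m <- arm_means(means$cost_intervention + adj("intervention"),
                 means$cost_control + adj("control"),
                 means$qaly_intervention, means$qaly_control)
  scenario_from_means(m, id = id %||% sprintf("scale_categories_%g", factor),
                      threshold = threshold, rounding_mode = rounding_mode)
}
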