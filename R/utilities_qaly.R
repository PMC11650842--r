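# EQ-5D-3L valuation and QALY computation.
#
# The EQ-5D-3L instrument describes a health state on five dimensions
# (mobility, self-care, usual activities, pain/discomfort, anxiety/depression)
# each at level 1 (no problems), 2 (some problems) or 3 (extreme problems).
# A value set (tariff) maps each of the 243 profiles to a utility anchored at
# 1 for full health (11111) and 0 for dead; additive TTO-derived tariffs
# subtract a decrement per dimension-level plus, optionally, a constant once
# any dimension is at level 3.

EQ5D_DIMENSIONS <- c("mobility", "self_care", "usual_activities",
                     "pain_discomfort", "anxiety_depression")

#' EQ-5D-3L value set
#'
#' An additive tariff: `utility = 1 - sum(decrements) - any3_constant * [any
#' level 3]`. Decrements for level 1 are zero by definition.
#'
#' @param decrements A 5 x 2 numeric matrix (rows in the order mobility,
#'   self-care, usual activities, pain/discomfort, anxiety/depression; columns
#'   for levels 2 and 3) of non-negative utility decrements.
#' @param any3_constant Additional decrement applied once when any dimension is
#'   at level 3. Default 0.
#' @param name Provenance label.
#' @return Object of class `eq5d_value_set` with a `floor` field (utility of
#'   the worst state 33333; may be negative for worse-than-dead states).
#' @export
eq5d_value_set <- function(decrements, any3_constant = 0, name = "unnamed") {
  decrements <- as.matrix(decrements)
  if (!all(dim(decrements) == c(5, 2)) || any(decrements < 0) || any(!is.finite(decrements))) {
    stop_domain("decrements must be a 5 x 2 non-negative matrix (levels 2 and 3)")
  }
  if (any(decrements[, 2] < decrements[, 1])) {
    stop_domain("level-3 decrements must be >= level-2 decrements")
  }
  assert_positive(any3_constant, "any3_constant", strict = FALSE)
  dimnames(decrements) <- list(EQ5D_DIMENSIONS, c("level2", "level3"))
  vs <- structure(
    list(name = name, decrements = decrements, any3_constant = any3_constant),
    class = "eq5d_value_set"
  )
  vs$floor <- utility_from_profile(rep(3L, 5), vs)
  vs
}

#' Toy documentation/testing tariff: 0.1 decrement per level step, no
#' level-3 constant (floor 0.0).
#' @rdname eq5d_value_set
#' @export
toy_value_set <- function() {
  eq5d_value_set(matrix(c(rep(0.1, 5), rep(0.2, 5)), ncol = 2), 0, name = "toy")
}

#' A synthetic TTO tariff with the typical structure of published South-Asian
#' EQ-5D-3L value sets (unequal dimension weights, an any-level-3 constant,
#' negative floor). The coefficients are illustrative, not a published tariff.
#' @rdname eq5d_value_set
#' @export
synthetic_tto_value_set <- function() {
  dec <- matrix(
    c(0.070, 0.090, 0.040, 0.080, 0.060,   # level 2
      0.198, 0.254, 0.104, 0.268, 0.202),  # level 3
    ncol = 2
  )
  eq5d_value_set(dec, any3_constant = 0.568, name = "synthetic-tto")
}

validate_profile <- function(profile) {
  profile <- as.integer(round(profile))
  if (length(profile) != 5 || any(!profile %in% 1:3)) {
    stop_domain("an EQ-5D-3L profile is five levels, each in {1, 2, 3}")
  }
  profile
}

#' Utility of an EQ-5D-3L profile under an additive value set
#'
#' @param profile Integer vector of 5 levels in `{1,2,3}`, or a 5-column
#'   matrix/data frame of profiles (one per row).
#' @param vs An [eq5d_value_set()].
#' @return Utility value(s); 1 for profile 11111 by construction.
#' @examples
#' utility_from_profile(c(1, 1, 1, 1, 1), toy_value_set())  # 1.0
#' utility_from_profile(c(2, 1, 1, 1, 1), toy_value_set())  # 0.9
#' @export
utility_from_profile <- function(profile, vs) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  if (is.matrix(profile) || is.data.frame(profile)) {
    m <- as.matrix(profile)
    if (ncol(m) != 5) stop_domain("profile matrix must have 5 columns")
    return(vapply(seq_len(nrow(m)), function(i) utility_from_profile(m[i, ], vs), numeric(1)))
  }
  profile <- validate_profile(profile)
  dec <- vs$decrements
  drop <- sum(ifelse(profile == 2, dec[, 1], 0) + ifelse(profile == 3, dec[, 2], 0))
  if (any(profile == 3)) drop <- drop + vs$any3_constant
  1 - drop
}

# Utilities of all 243 profiles, used for nearest-profile projection when the
# generator is asked to emit discrete profiles.
all_profile_utilities <- function(vs) {
  grid <- as.matrix(expand.grid(rep(list(1:3), 5)))
  colnames(grid) <- EQ5D_DIMENSIONS
  data.frame(grid, utility = utility_from_profile(grid, vs))
}

#' Read/write a value set as plain CSV
#'
#' Format: columns `dimension`, `level`, `decrement`; dimension `any_level_3`
#' (level `NA`) holds the optional constant term.
#' @param path CSV path.
#' @param vs Value set to write.
#' @param name Label for the value set read.
#' @export
read_value_set <- function(path, name = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("dimension", "level", "decrement") %in% names(df))) {
    stop_domain("value-set CSV needs columns dimension, level, decrement")
  }
  const <- df$decrement[df$dimension == "any_level_3"]
  body <- df[df$dimension %in% EQ5D_DIMENSIONS, ]
  dec <- matrix(0, 5, 2, dimnames = list(EQ5D_DIMENSIONS, c("level2", "level3")))
  for (i in seq_len(nrow(body))) {
    lv <- body$level[i]
    if (!lv %in% 2:3) stop_domain("value-set rows must be for levels 2 or 3")
    dec[body$dimension[i], lv - 1] <- body$decrement[i]
  }
  eq5d_value_set(dec, if (length(const)) const[1] else 0, name = name)
}

#' @rdname read_value_set
#' @export
write_value_set <- function(vs, path) {
  dec <- vs$decrements
  df <- data.frame(
    dimension = c(rep(rownames(dec), 2), "any_level_3"),
    level = c(rep(2L, 5), rep(3L, 5), NA_integer_),
    decrement = c(dec[, 1], dec[, 2], vs$any3_constant)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' QALYs by trapezoidal area under the utility curve
#'
#' For utilities measured at `times` (years since baseline, starting at 0),
#' the quality-adjusted life years accrued are the trapezoidal area under the
#' piecewise-linear utility curve. For two timepoints over a half-year horizon
#' this is `0.5 * (u0 + u1) / 2`.
#'
#' @param utilities Utility at each timepoint (may be negative for
#'   worse-than-dead states; never floored at 0).
#' @param times Strictly increasing timepoints in years, starting at 0.
#' @return QALYs over the horizon (at most `max(times)`).
#' @examples
#' qaly_auc(c(0.8, 0.6), c(0, 0.5))  # 0.35
#' @export
qaly_auc <- function(utilities, times) {
  if (length(utilities) != length(times)) {
    stop_domain("utilities and times must have the same length")
  }
  if (length(times) < 2 || times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop_domain("times must start at 0 and be strictly increasing")
  }
  sum(diff(times) * (head(utilities, -1) + utilities[-1]) / 2)
}

#' Vectorised two-timepoint QALYs (baseline + one follow-up)
#'
#' Trapezoidal QALYs over `horizon` years for a whole trial at once;
#' equivalent to [qaly_auc()] applied row-wise with `times = c(0, horizon)`.
#' @param utility_baseline,utility_followup Utility vectors.
#' @param horizon Trial horizon in years. Default 0.5.
#' @return QALY vector (NA where the follow-up utility is missing).
#' @export
participant_qalys <- function(utility_baseline, utility_followup, horizon = 0.5) {
  assert_positive(horizon, "horizon")
  horizon * (utility_baseline + utility_followup) / 2
}

#' Descriptive EQ-VAS summary per arm and timepoint
#'
#' The EQ-VAS is a 0-100 self-rated health score; it is reported descriptively
#' (mean, SD), with missing responses excluded and counted.
#'
#' @param records Data frame with columns `arm`, `vas_baseline`,
#'   `vas_followup`.
#' @return Data frame: arm, timepoint, n, n_missing, mean, sd. Cells with no
#'   observed values carry `NA` (not zero) and `computable = FALSE`.
#' @export
vas_summary <- function(records) {
  vals <- c(records$vas_baseline, records$vas_followup)
  if (any(vals < 0 | vals > 100, na.rm = TRUE)) {
    stop_domain("VAS scores must lie in [0, 100]")
  }
  out <- expand.grid(arm = unique(records$arm),
                     timepoint = c("baseline", "followup"),
                     stringsAsFactors = FALSE)
  stats_for <- function(arm, tp) {
    v <- records[records$arm == arm, paste0("vas_", tp)]
    obs <- v[!is.na(v)]
    data.frame(n = length(obs), n_missing = sum(is.na(v)),
               mean = if (length(obs)) mean(obs) else NA_real_,
               sd = if (length(obs) > 1) sd(obs) else if (length(obs) == 1) 0 else NA_real_,
               computable = length(obs) > 0)
  }
  cbind(out, do.call(rbind, Map(stats_for, out$arm, out$timepoint)))
}
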