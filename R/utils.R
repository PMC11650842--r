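# Internal helpers shared across modules.

# Commercial rounding (half away from zero), as used in printed report tables.
# base::round() rounds half to even, which disagrees with how published
# cost-effectiveness tables are typically rounded (e.g. 0.00825 -> 0.0083).
# A tiny epsilon guards against binary representation of decimal halves.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Deterministic per-stage substream seeds derived from one master seed.
# Keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  stage_num <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 48271 + stage_num * 1009) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Percentile bootstrap interval by the (B+1) order-statistic convention
# (Davison & Hinkley): bounds are elements of the sorted draw set.
percentile_ci <- function(x, conf = 0.95) {
  a <- (1 - conf) / 2
  B <- length(x)
  s <- sort(x)
  c(s[max(1, floor((B + 1) * a))], s[min(B, ceiling((B + 1) * (1 - a)))])
}

stop_domain <- function(...) stop(..., call. = FALSE)

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop_domain(name, " must be a single number in [0, 1], got ", format(x))
  }
  invisible(x)
}

assert_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) stop_domain(name, " must be ", if (strict) "strictly positive" else "non-negative")
  invisible(x)
}

# Moment-matched shape/scale for a gamma with given mean and sd.
gamma_shape_scale <- function(mean, sd) {
  assert_positive(mean, "gamma mean")
  assert_positive(sd, "gamma sd")
  list(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

# Shape parameters of a Beta rescaled to [lo, hi] with target mean and sd on
# the original scale. Errors when the (mean, sd) pair is infeasible.
beta_shapes <- function(mean, sd, lo, hi) {
  stopifnot(hi > lo)
  m <- (mean - lo) / (hi - lo)
  v <- (sd / (hi - lo))^2
  if (m <= 0 || m >= 1) stop_domain("beta mean outside (", lo, ", ", hi, ")")
  if (v >= m * (1 - m)) stop_domain("beta sd infeasible for mean ", mean, " on [", lo, ", ", hi, "]")
  k <- m * (1 - m) / v - 1
  list(shape1 = m * k, shape2 = (1 - m) * k)
}
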