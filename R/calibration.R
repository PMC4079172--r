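# Calibration of raw effect sizes (odds ratios) into fuzzy outcome
# memberships, via a four-level step scheme on the logged-OR scale.

#' Define an effect-size calibration scheme
#'
#' Raw odds ratios are logged and mapped onto discrete membership levels in
#' the outcome set by ordered breakpoints. With the defaults:
#' full membership (1.0) when log(OR) > 0.7; more in than out (0.666) when
#' 0.4 < log(OR) <= 0.7; more out than in (0.333) when 0 < log(OR) <= 0.4;
#' fully out (0.0) when log(OR) <= 0. Boundary values fall to the lower
#' level (the inequalities are `>` above, `<=` below).
#'
#' @param log_base `"natural"` (default) or `"base10"`: the logarithm
#'   applied to the odds ratio before thresholding.
#' @param thresholds Strictly decreasing breakpoints on the logged scale.
#' @param levels Strictly decreasing membership levels in \[0, 1\]; one more
#'   level than there are thresholds.
#' @return An object of class `calibration_scheme`.
#' @export
calibration_scheme <- function(log_base = c("natural", "base10"),
                               thresholds = c(0.7, 0.4, 0),
                               levels = c(1, 0.666, 0.333, 0)) {
  log_base <- match.arg(log_base)
  if (length(levels) != length(thresholds) + 1L) {
    stop("need exactly one more level than thresholds", call. = FALSE)
  }
  if (any(diff(thresholds) >= 0)) {
    stop("thresholds must be strictly decreasing", call. = FALSE)
  }
  if (any(diff(levels) >= 0) || any(levels < 0 | levels > 1)) {
    stop("levels must be strictly decreasing memberships in [0,1]", call. = FALSE)
  }
  structure(list(log_base = log_base, thresholds = thresholds, levels = levels),
            class = "calibration_scheme")
}

#' Calibrate raw odds ratios into fuzzy outcome memberships
#'
#' Applies the step scheme of [calibration_scheme()]: the membership is
#' `levels[k + 1]` where `k` is the number of thresholds at or above the
#' logged odds ratio. The mapping is a monotone non-decreasing step
#' function of the raw effect size.
#'
#' @param raw_or Positive odds ratio(s).
#' @param scheme A [calibration_scheme()]; defaults reproduce the four-level
#'   natural-log scheme.
#' @return Numeric vector of membership levels, one per input.
#' @examples
#' calibrate_effect(c(8.458, 0.463, 1.927)) # 1.000, 0.000, 0.666
#' @export
calibrate_effect <- function(raw_or, scheme = calibration_scheme()) {
  stopifnot(inherits(scheme, "calibration_scheme"))
  if (!is.numeric(raw_or) || any(is.na(raw_or)) || any(raw_or <= 0)) {
    stop("odds ratios must be positive", call. = FALSE)
  }
  lor <- if (scheme$log_base == "natural") log(raw_or) else log10(raw_or)
  # small tolerance so that e.g. log(exp(0.7)) lands on its threshold exactly
  k <- vapply(lor, function(v) sum(scheme$thresholds >= v - 1e-9), integer(1))
  scheme$levels[k + 1L]
}

#' Fuzzy set negation
#'
#' The standard fuzzy complement `1 - m`. Involutive and order-reversing;
#' the crossover 0.5 is its fixed point.
#'
#' @param m Membership value(s) in \[0, 1\].
#' @return `1 - m`.
#' @export
negate_membership <- function(m) {
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0 | m > 1)) {
    stop("memberships must lie in [0,1]", call. = FALSE)
  }
  1 - m
}

#' Calibrate the outcome column of a data table
#'
#' For a table whose outcome column holds raw odds ratios (schema declared
#' with `outcome_calibrated = FALSE`), replaces the column with calibrated
#' fuzzy memberships and keeps the raw values in a raw-effect column.
#'
#' @param table A `qca_data` object with an uncalibrated outcome.
#' @param scheme A [calibration_scheme()].
#' @return A `qca_data` object with calibrated outcome memberships.
#' @export
calibrate_outcome <- function(table, scheme = calibration_scheme()) {
  stopifnot(inherits(table, "qca_data"))
  if (isTRUE(table$outcome$calibrated)) {
    stop("outcome is already calibrated", call. = FALSE)
  }
  raw <- table$cases[[table$outcome$name]]
  if (any(raw <= 0)) stop("odds ratios must be positive", call. = FALSE)
  eff_col <- table$raw_effect %||% "raw_effect"
  table$cases[[eff_col]] <- raw
  table$raw_effect <- eff_col
  table$cases[[table$outcome$name]] <- calibrate_effect(raw, scheme)
  table$outcome$calibrated <- TRUE
  ord <- c("case_id", table$conditions$name, eff_col, table$outcome$name)
  table$cases <- table$cases[, ord]
  validate_qca_data(table)
}
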