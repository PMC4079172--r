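# Coverage and consistency of solutions and their component configurations.
# Fuzzy forms: consistency(X -> Y) = sum(min(x,y))/sum(x);
#              coverage(X -> Y)    = sum(min(x,y))/sum(y).
# Coverage and consistency are dual: coverage(X -> Y) = consistency(Y -> X).

#' Coverage and consistency of membership vectors
#'
#' Low-level set-relation metrics on two membership vectors.
#' `set_consistency(x, y)` measures how far `x` is a fuzzy subset of `y`
#' (sufficiency of X for Y); `set_coverage(x, y)` how much of `y` is
#' accounted for by `x`. `set_coverage(x, y) == set_consistency(y, x)`.
#'
#' @param x,y Numeric membership vectors of equal length, values in
#'   \[0, 1\].
#' @return A scalar in \[0, 1\]; `NA_real_` when the denominator is zero.
#' @export
set_consistency <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (sum(x) == 0) return(NA_real_)
  sum(pmin(x, y)) / sum(x)
}

#' @rdname set_consistency
#' @export
set_coverage <- function(x, y) {
  set_consistency(y, x)
}

#' Solution coverage
#'
#' The proportion of outcome membership accounted for by the solution:
#' `sum(min(s, y)) / sum(y)` with `s` the expression membership of each
#' case. For crisp sets this is the fraction of outcome cases exhibiting
#' the solution.
#'
#' @param table A `qca_data` object with calibrated outcome.
#' @param expr A `qca_expr` (or `qca_config`).
#' @param outcome_negated Score against the negated outcome?
#' @return Coverage in \[0, 1\].
#' @export
solution_coverage <- function(table, expr, outcome_negated = FALSE) {
  sy <- solution_xy(table, expr, outcome_negated)
  if (sum(sy$y) == 0) {
    stop("undefined metric: the outcome has zero total membership", call. = FALSE)
  }
  set_coverage(sy$s, sy$y)
}

#' Solution consistency
#'
#' The proportion of solution membership that obtains the outcome:
#' `sum(min(s, y)) / sum(s)`.
#'
#' @inheritParams solution_coverage
#' @return Consistency in \[0, 1\].
#' @export
solution_consistency <- function(table, expr, outcome_negated = FALSE) {
  sy <- solution_xy(table, expr, outcome_negated)
  if (sum(sy$s) == 0) {
    stop("undefined metric: the solution has zero total membership", call. = FALSE)
  }
  set_consistency(sy$s, sy$y)
}

solution_xy <- function(table, expr, outcome_negated = FALSE) {
  stopifnot(inherits(table, "qca_data"))
  if (inherits(expr, "qca_config")) expr <- qca_expr(list(expr))
  list(s = expr_membership(table, expr),
       y = outcome_memberships(table, negated = outcome_negated))
}

#' Per-component and overall solution metrics
#'
#' For each term (configuration) of a solution: raw coverage
#' `sum(min(c, y))/sum(y)`, unique coverage — the drop in solution coverage
#' when the term is removed, `[sum(min(s, y)) - sum(min(s_without, y))] /
#' sum(y)` — and the term's own consistency `sum(min(c, y))/sum(c)`.
#' Overall solution coverage and consistency are computed on the full
#' disjunction. For a single-term solution unique coverage equals raw
#' coverage equals solution coverage.
#'
#' @param table A `qca_data` object with calibrated outcome.
#' @param solution A `qca_solution` (from [minimise()]) or a `qca_expr`.
#' @param outcome_negated Score against the negated outcome?
#' @return An object of class `qca_metrics`: list with `components` (data
#'   frame: `component`, `raw_coverage`, `unique_coverage`,
#'   `consistency`), `solution_coverage`, `solution_consistency`.
#' @export
component_coverages <- function(table, solution, outcome_negated = FALSE) {
  expr <- if (inherits(solution, "qca_solution")) solution$expression else solution
  conds <- if (inherits(solution, "qca_solution")) solution$conditions else
    condition_names(table)
  stopifnot(inherits(expr, "qca_expr"), length(expr) >= 1L)
  y <- outcome_memberships(table, negated = outcome_negated)
  if (sum(y) == 0) {
    stop("undefined metric: the outcome has zero total membership", call. = FALSE)
  }
  s <- expr_membership(table, expr)
  sol_cov <- sum(pmin(s, y)) / sum(y)
  sol_con <- if (sum(s) > 0) sum(pmin(s, y)) / sum(s) else NA_real_

  comp <- do.call(rbind, lapply(seq_along(expr), function(i) {
    ci <- config_membership(table, expr[[i]])
    without <- expr[-i]
    s_wo <- if (length(without)) {
      expr_membership(table, qca_expr(without))
    } else rep(0, length(y))
    data.frame(
      component = format_label(expr[[i]], conds),
      raw_coverage = sum(pmin(ci, y)) / sum(y),
      unique_coverage = (sum(pmin(s, y)) - sum(pmin(s_wo, y))) / sum(y),
      consistency = if (sum(ci) > 0) sum(pmin(ci, y)) / sum(ci) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(comp) <- NULL
  structure(list(components = comp,
                 solution_coverage = sol_cov,
                 solution_consistency = sol_con),
            class = "qca_metrics")
}

#' @export
print.qca_metrics <- function(x, ...) {
  disp <- x$components
  for (col in c("raw_coverage", "unique_coverage", "consistency")) {
    disp[[col]] <- fmt_membership(disp[[col]])
  }
  print(disp, row.names = FALSE)
  cat(sprintf("Solution coverage %s, solution consistency %s\n",
              fmt_membership(x$solution_coverage),
              fmt_membership(x$solution_consistency)))
  invisible(x)
}
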