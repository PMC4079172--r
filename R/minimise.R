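# Exact Boolean minimisation of positive truth-table rows:
# Quine-McCluskey prime implicants + essential-prime / Petrick-style exact
# cover. k is small in evidence synthesis (hard cap 8), so exact search is
# affordable and preferred over heuristics.

as_corner_matrix <- function(x, conditions = NULL) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "integer"
  if (!is.null(conditions)) {
    if (is.null(colnames(x))) colnames(x) <- conditions else
      x <- x[, conditions, drop = FALSE]
  }
  if (any(!(x %in% c(0L, 1L)))) stop("corners must be 0/1", call. = FALSE)
  x
}

corner_strings <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(character(0))
  apply(m, 1, paste, collapse = "")
}

pattern_covers <- function(pattern, corner) {
  p <- strsplit(pattern, "")[[1]]
  q <- strsplit(corner, "")[[1]]
  all(p == "-" | p == q)
}

merge_patterns <- function(a, b) {
  pa <- strsplit(a, "")[[1]]
  pb <- strsplit(b, "")[[1]]
  if (any((pa == "-") != (pb == "-"))) return(NULL)
  diff <- which(pa != pb)
  if (length(diff) != 1L) return(NULL)
  pa[diff] <- "-"
  paste(pa, collapse = "")
}

#' Prime implicants of a corner set
#'
#' Iteratively merges corners (and merged cubes) differing in exactly one
#' position until no merge applies; the unmerged cubes are the prime
#' implicants — the maximal implicants covering only the given corners.
#'
#' @param minterms Matrix/data frame of 0/1 corners (one per row) the
#'   function must be true on; columns are conditions.
#' @param dont_cares Optional corners the implicants may also cover
#'   (logical remainders under the parsimonious policy).
#' @return Character vector of patterns over `{"0","1","-"}` (dash =
#'   condition eliminated), sorted deterministically.
#' @export
prime_implicants <- function(minterms, dont_cares = NULL) {
  minterms <- as_corner_matrix(minterms)
  dont_cares <- as_corner_matrix(dont_cares)
  current <- unique(c(corner_strings(minterms), corner_strings(dont_cares)))
  if (!length(current)) stop("no corners given", call. = FALSE)
  primes <- character(0)
  while (length(current)) {
    merged <- rep(FALSE, length(current))
    nxt <- character(0)
    if (length(current) > 1L) {
      for (i in seq_len(length(current) - 1L)) {
        for (j in seq(i + 1L, length(current))) {
          m <- merge_patterns(current[i], current[j])
          if (!is.null(m)) {
            merged[i] <- merged[j] <- TRUE
            nxt <- c(nxt, m)
          }
        }
      }
    }
    primes <- c(primes, current[!merged])
    current <- unique(nxt)
  }
  sort(unique(primes))
}

pattern_literals <- function(pattern) {
  sum(strsplit(pattern, "")[[1]] != "-")
}

#' Minimal cover of minterms by prime implicants
#'
#' Essential primes (sole coverers of some minterm) are selected first; the
#' residual cover problem is solved exactly by exhaustive subset search
#' (Petrick-style), minimising first the number of implicants, then the
#' total literal count, with a deterministic lexicographic tie-break on the
#' patterns.
#'
#' @param primes Character vector of implicant patterns.
#' @param minterms Matrix of 0/1 corners that must be covered.
#' @return Character vector: the selected patterns.
#' @export
select_cover <- function(primes, minterms) {
  minterms <- as_corner_matrix(minterms)
  mts <- unique(corner_strings(minterms))
  chart <- vapply(mts, function(mt)
    vapply(primes, pattern_covers, logical(1), corner = mt),
    logical(length(primes)))
  if (length(primes) == 1L) chart <- matrix(chart, nrow = 1L, dimnames = list(primes, mts))
  if (!all(colSums(chart) > 0)) {
    stop("internal error: minterm not covered by any prime implicant", call. = FALSE)
  }
  essential <- unique(primes[apply(chart, 2, function(col) {
    if (sum(col) == 1L) which(col) else NA_integer_
  }) |> stats::na.omit()])
  covered <- if (length(essential)) {
    apply(chart[essential, , drop = FALSE], 2, any)
  } else rep(FALSE, length(mts))

  remaining_mts <- mts[!covered]
  if (!length(remaining_mts)) return(sort_patterns(essential))

  candidates <- setdiff(primes, essential)
  candidates <- candidates[vapply(candidates, function(p)
    any(vapply(remaining_mts, pattern_covers, logical(1), pattern = p)),
    logical(1))]

  best <- NULL
  for (size in seq_along(candidates)) {
    combos <- utils::combn(candidates, size, simplify = FALSE)
    covers <- Filter(function(sel) {
      all(vapply(remaining_mts, function(mt)
        any(vapply(sel, pattern_covers, logical(1), corner = mt)), logical(1)))
    }, combos)
    if (length(covers)) {
      costs <- vapply(covers, function(sel) sum(vapply(sel, pattern_literals,
                                                       numeric(1))), numeric(1))
      covers <- covers[costs == min(costs)]
      keys <- vapply(covers, function(sel) paste(sort(sel), collapse = "|"),
                     character(1))
      best <- covers[[order(keys)[1]]]
      break
    }
  }
  if (is.null(best)) {
    stop("internal error: no cover found", call. = FALSE)
  }
  sort_patterns(c(essential, best))
}

# deterministic display order: by the first bound condition, then pattern
sort_patterns <- function(patterns) {
  if (!length(patterns)) return(patterns)
  first_lit <- vapply(patterns, function(p) {
    idx <- which(strsplit(p, "")[[1]] != "-")
    if (length(idx)) idx[1] else 0L
  }, integer(1))
  patterns[order(first_lit, patterns)]
}

pattern_to_config <- function(pattern, conditions) {
  bits <- strsplit(pattern, "")[[1]]
  qca_config(present = conditions[bits == "1"],
             absent = conditions[bits == "0"])
}

#' Minimise positive truth-table rows to a Boolean solution
#'
#' Reduces the positive corners to a minimal disjunction of prime
#' implicants. Under the `conservative` policy (default) logical remainders
#' are treated as false and the solution is logically equivalent to the
#' positive-row set; under `parsimonious` the remainders enter as
#' don't-cares, which can only shorten the solution (it stays true on every
#' positive corner and false on every negative one).
#'
#' @param positive_rows Matrix/data frame of 0/1 corners classified
#'   positive (columns named by condition).
#' @param remainder_rows Corners with no observed cases (may be `NULL`).
#' @param conditions Character vector naming the corner columns, in display
#'   order; taken from `colnames(positive_rows)` when omitted.
#' @param policy `"conservative"` or `"parsimonious"`.
#' @return An object of class `qca_solution`: list with `expression` (a
#'   [qca_expr()]), `implicants` (patterns), `policy`, `minterms`,
#'   `dont_cares`, `conditions`.
#' @export
minimise <- function(positive_rows, remainder_rows = NULL, conditions = NULL,
                     policy = c("conservative", "parsimonious")) {
  policy <- match.arg(policy)
  if (is.null(positive_rows) ||
      (!is.null(dim(positive_rows)) && nrow(positive_rows) == 0L) ||
      length(positive_rows) == 0L) {
    stop("no configuration passed the consistency cutoff: nothing to minimise",
         call. = FALSE)
  }
  positive_rows <- as_corner_matrix(positive_rows, conditions)
  conditions <- conditions %||% colnames(positive_rows) %||%
    paste0("C", seq_len(ncol(positive_rows)))
  remainder_rows <- as_corner_matrix(remainder_rows, conditions)
  if (!is.null(remainder_rows) && nrow(remainder_rows)) {
    overlap <- intersect(corner_strings(positive_rows),
                         corner_strings(remainder_rows))
    if (length(overlap)) {
      stop("positive and remainder corner sets must be disjoint", call. = FALSE)
    }
  }
  dont_cares <- if (policy == "parsimonious") remainder_rows else NULL
  primes <- prime_implicants(positive_rows, dont_cares)
  chosen <- select_cover(primes, positive_rows)
  terms <- lapply(chosen, pattern_to_config, conditions = conditions)
  structure(list(expression = qca_expr(terms),
                 implicants = chosen,
                 policy = policy,
                 minterms = positive_rows,
                 dont_cares = dont_cares,
                 conditions = conditions),
            class = "qca_solution")
}

#' Minimise a built truth table
#'
#' Convenience wrapper: takes the positive rows of a [build_truth_table()]
#' result as minterms and its remainder rows as don't-cares (parsimonious
#' policy only), then attaches coverage/consistency metrics computed on the
#' source data table.
#'
#' @param truthtable A `qca_truth_table`.
#' @param policy `"conservative"` or `"parsimonious"`.
#' @return A `qca_solution` with a `metrics` element (see
#'   [component_coverages()]).
#' @export
minimise_truth_table <- function(truthtable,
                                 policy = c("conservative", "parsimonious")) {
  stopifnot(inherits(truthtable, "qca_truth_table"))
  policy <- match.arg(policy)
  conds <- tt_conditions(truthtable)
  pos <- as.matrix(truthtable[truthtable$outcome_class == "positive", conds,
                              drop = FALSE])
  rem <- as.matrix(truthtable[truthtable$outcome_class == "remainder", conds,
                              drop = FALSE])
  sol <- minimise(pos, remainder_rows = rem, conditions = conds, policy = policy)
  sol$metrics <- component_coverages(
    tt_data(truthtable), sol,
    outcome_negated = tt_settings(truthtable)$outcome_negated)
  sol
}

#' @export
print.qca_solution <- function(x, ...) {
  cat(sprintf("Solution (%s policy): %s\n", x$policy,
              format_label(x$expression, x$conditions)))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}
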