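# Fuzzy Boolean set algebra over conditions, and the field's configuration
# label notation: * = AND, + = OR, ~ = NOT (e.g. "Empowerment*Lay-led*~Design").

#' Build a configuration (conjunction of condition literals)
#'
#' A configuration is a conjunction of condition literals, each either
#' present or absent (negated). The empty configuration is the universal
#' set (membership 1 everywhere).
#'
#' @param present Character vector of conditions required present.
#' @param absent Character vector of conditions required absent.
#' @return An object of class `qca_config`: a named logical vector, `TRUE`
#'   for present literals, `FALSE` for absent ones.
#' @export
qca_config <- function(present = character(0), absent = character(0)) {
  lits <- c(stats::setNames(rep(TRUE, length(present)), present),
            stats::setNames(rep(FALSE, length(absent)), absent))
  if (anyDuplicated(tolower(names(lits)))) {
    stop("a condition may appear at most once in a configuration",
         call. = FALSE)
  }
  structure(lits, class = "qca_config")
}

#' Build an expression (disjunction of configurations)
#'
#' @param ... `qca_config` objects, the terms of the disjunction.
#' @return An object of class `qca_expr`.
#' @export
qca_expr <- function(...) {
  terms <- list(...)
  if (length(terms) == 1L && is.list(terms[[1]]) && !inherits(terms[[1]], "qca_config")) {
    terms <- terms[[1]]
  }
  if (!length(terms)) stop("an expression needs at least one term", call. = FALSE)
  if (!all(vapply(terms, inherits, logical(1), "qca_config"))) {
    stop("expression terms must be qca_config objects", call. = FALSE)
  }
  keys <- vapply(terms, function(tm) term_key(tm), character(1))
  if (anyDuplicated(keys)) stop("duplicate terms in expression", call. = FALSE)
  structure(terms, class = "qca_expr")
}

term_key <- function(config) {
  nm <- tolower(names(config))
  o <- order(nm)
  paste(ifelse(unclass(config)[o], "", "~"), nm[o], sep = "", collapse = "*")
}

# resolve a condition name case-insensitively against declared names
resolve_condition <- function(name, declared) {
  hit <- which(tolower(declared) == tolower(name))
  if (length(hit) != 1L) {
    stop(sprintf("unknown condition '%s'", name), call. = FALSE)
  }
  declared[hit]
}

as_condition_names <- function(conditions) {
  if (inherits(conditions, "qca_data")) return(conditions$conditions$name)
  if (inherits(conditions, "qca_schema")) return(conditions$conditions$name)
  if (is.data.frame(conditions)) return(conditions$name)
  as.character(conditions)
}

#' Fuzzy membership of cases in a configuration
#'
#' The fuzzy conjunction: the minimum over literals of the condition
#' membership (present literal) or its complement `1 - m` (absent literal).
#' The empty configuration evaluates to 1 (universal set). For crisp cases
#' this reduces to ordinary Boolean evaluation.
#'
#' @param case A named numeric membership vector for one case, a numeric
#'   matrix of memberships (cases in rows, conditions in columns), or a
#'   `qca_data` table (then all cases are evaluated).
#' @param config A `qca_config`.
#' @return Numeric membership(s) in \[0, 1\].
#' @export
config_membership <- function(case, config) {
  stopifnot(inherits(config, "qca_config"))
  m <- case_matrix(case)
  out <- rep(1, nrow(m))
  for (i in seq_along(config)) {
    col <- resolve_condition(names(config)[i], colnames(m))
    v <- m[, col]
    out <- pmin(out, if (unclass(config)[i]) v else 1 - v)
  }
  stats::setNames(out, rownames(m))
}

#' Fuzzy membership of cases in an expression
#'
#' The fuzzy disjunction: the maximum over the expression's terms of
#' [config_membership()].
#'
#' @inheritParams config_membership
#' @param expr A `qca_expr`.
#' @return Numeric membership(s) in \[0, 1\].
#' @export
expr_membership <- function(case, expr) {
  stopifnot(inherits(expr, "qca_expr"))
  m <- case_matrix(case)
  vals <- vapply(expr, function(tm) config_membership(m, tm), numeric(nrow(m)))
  if (nrow(m) == 1L) vals <- matrix(vals, nrow = 1L)
  stats::setNames(apply(vals, 1, max), rownames(m))
}

case_matrix <- function(case) {
  if (inherits(case, "qca_data")) return(membership_matrix(case))
  if (is.matrix(case)) return(case)
  if (is.numeric(case) && !is.null(names(case))) {
    return(matrix(case, nrow = 1L, dimnames = list(NULL, names(case))))
  }
  stop("cases must be a named membership vector, a matrix, or a qca_data table",
       call. = FALSE)
}

#' Format configurations and expressions as set labels
#'
#' Literals are joined by `*`, absent literals prefixed by `~`, and
#' disjunction terms joined by `" + "`. When `conditions` is supplied the
#' literals are ordered (and cased) by the declared condition order, giving
#' deterministic labels; otherwise the stored order is used. The empty
#' configuration formats as `"1"` (the universal set).
#'
#' @param x A `qca_config` or `qca_expr`.
#' @param conditions Optional condition declarations (a `qca_data`,
#'   `qca_schema`, condition data frame, or character vector) fixing order
#'   and display case.
#' @return A single string.
#' @export
format_label <- function(x, conditions = NULL) {
  UseMethod("format_label")
}

#' @export
format_label.qca_config <- function(x, conditions = NULL) {
  if (!length(x)) return("1")
  nms <- names(x)
  pol <- unclass(x)
  if (!is.null(conditions)) {
    declared <- as_condition_names(conditions)
    nms <- vapply(nms, resolve_condition, character(1), declared = declared)
    o <- order(match(tolower(nms), tolower(declared)))
    nms <- nms[o]; pol <- pol[o]
  }
  paste0(ifelse(pol, "", "~"), nms, collapse = "*")
}

#' @export
format_label.qca_expr <- function(x, conditions = NULL) {
  paste(vapply(x, format_label, character(1), conditions = conditions),
        collapse = " + ")
}

#' @export
print.qca_config <- function(x, ...) {
  cat(format_label(x), "\n")
  invisible(x)
}

#' @export
print.qca_expr <- function(x, ...) {
  cat(format_label(x), "\n")
  invisible(x)
}

#' Parse a set label into an expression
#'
#' Inverse of [format_label()]: accepts `*` (AND), `+` (OR) and `~` (NOT)
#' notation, with condition names matched case-insensitively against the
#' declared conditions. `"1"` parses to the universal (empty) configuration.
#'
#' @param text A label such as `"Intensity + Quality"` or
#'   `"~Empowerment*Lay-led*Design"`.
#' @param conditions Condition declarations to resolve names against.
#' @return A `qca_expr` whose [format_label()] equals the canonicalised
#'   input.
#' @export
parse_label <- function(text, conditions) {
  declared <- as_condition_names(conditions)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("parse error: empty expression", call. = FALSE)
  }
  term_texts <- strsplit(text, "+", fixed = TRUE)[[1]]
  terms <- lapply(seq_along(term_texts), function(ti) {
    tt <- trimws(term_texts[ti])
    if (!nzchar(tt)) {
      stop(sprintf("parse error: empty term at position %d", ti), call. = FALSE)
    }
    if (tt == "1") return(qca_config())
    lit_texts <- trimws(strsplit(tt, "*", fixed = TRUE)[[1]])
    present <- character(0); absent <- character(0)
    for (li in seq_along(lit_texts)) {
      lt <- lit_texts[li]
      if (!nzchar(lt)) {
        stop(sprintf("parse error: empty literal in term %d", ti), call. = FALSE)
      }
      neg <- startsWith(lt, "~")
      nm <- trimws(sub("^~\\s*", "", lt))
      if (!nzchar(nm)) {
        stop(sprintf("parse error: bare '~' in term %d", ti), call. = FALSE)
      }
      nm <- resolve_condition(nm, declared)
      if (tolower(nm) %in% tolower(c(present, absent))) {
        stop(sprintf("parse error: condition '%s' appears twice in term %d",
                     nm, ti), call. = FALSE)
      }
      if (neg) absent <- c(absent, nm) else present <- c(present, nm)
    }
    qca_config(present = present, absent = absent)
  })
  qca_expr(terms)
}
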