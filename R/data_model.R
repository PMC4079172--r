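# Case-by-condition data tables: one row per study, columns for condition
# memberships (crisp {0,1} or fuzzy [0,1]) and a single outcome.

#' Declare a condition
#'
#' A condition is a characteristic of a case (study) used as an explanatory
#' factor. Crisp conditions admit only memberships 0 and 1; fuzzy conditions
#' admit any membership in \[0, 1\].
#'
#' @param name Condition name. Non-empty; matched case-insensitively,
#'   preserved as given for display.
#' @param kind `"crisp"` or `"fuzzy"`.
#' @param description Optional free-text description.
#' @return A one-row data frame with columns `name`, `kind`, `description`.
#' @export
condition_def <- function(name, kind = c("crisp", "fuzzy"), description = NA_character_) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(trimws(name))) {
    stop("condition name must be a non-empty string", call. = FALSE)
  }
  data.frame(name = name, kind = kind, description = description,
             stringsAsFactors = FALSE)
}

#' Declare the schema of a QCA data table
#'
#' The schema names the conditions (with their kind), the single outcome
#' column, whether that column is already a calibrated fuzzy membership or a
#' raw effect size, and an optional raw effect-size column carried alongside
#' a pre-calibrated outcome.
#'
#' @param conditions Either a data frame as returned by [condition_def()]
#'   (rows may be stacked with `rbind`) or a named character vector such as
#'   `c(Empowerment = "crisp", Quality = "fuzzy")`.
#' @param outcome Name of the outcome column.
#' @param outcome_calibrated `TRUE` if the outcome column already holds fuzzy
#'   memberships; `FALSE` if it holds raw odds ratios to be calibrated with
#'   [calibrate_effect()].
#' @param raw_effect Optional name of a raw effect-size (odds-ratio) column
#'   kept for reference when the outcome is pre-calibrated.
#' @return An object of class `qca_schema`.
#' @export
qca_schema <- function(conditions, outcome, outcome_calibrated = TRUE,
                       raw_effect = NULL) {
  if (is.character(conditions)) {
    if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
      stop("`conditions` given as a character vector must be named (name = kind)",
           call. = FALSE)
    }
    conditions <- do.call(rbind, mapply(condition_def, names(conditions),
                                        unname(conditions), SIMPLIFY = FALSE))
    rownames(conditions) <- NULL
  }
  stopifnot(is.data.frame(conditions),
            all(c("name", "kind") %in% names(conditions)))
  if (!all(conditions$kind %in% c("crisp", "fuzzy"))) {
    stop("condition kind must be 'crisp' or 'fuzzy'", call. = FALSE)
  }
  if (anyDuplicated(tolower(conditions$name))) {
    stop("condition names must be unique (case-insensitively)", call. = FALSE)
  }
  if (!is.character(outcome) || length(outcome) != 1L || !nzchar(outcome)) {
    stop("exactly one outcome column name is required", call. = FALSE)
  }
  if (outcome %in% conditions$name) {
    stop("outcome name collides with a condition name", call. = FALSE)
  }
  if (!"description" %in% names(conditions)) conditions$description <- NA_character_
  structure(list(conditions = conditions[, c("name", "kind", "description")],
                 outcome = list(name = outcome,
                                calibrated = isTRUE(outcome_calibrated)),
                 raw_effect = raw_effect),
            class = "qca_schema")
}

#' Read a schema declaration from a YAML file
#'
#' The document lists `conditions` (each with `name` and `kind`), an
#' `outcome` (with `name` and `calibrated`), and optionally `raw_effect` and
#' `delimiter`.
#'
#' @param path Path to the YAML file.
#' @return A `qca_schema`; any `delimiter` entry is attached as the
#'   `"delimiter"` attribute.
#' @export
read_schema <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$conditions) || is.null(doc$outcome)) {
    stop("schema file must declare 'conditions' and 'outcome'", call. = FALSE)
  }
  conds <- do.call(rbind, lapply(doc$conditions, function(cd) {
    condition_def(cd$name, cd$kind %||% "crisp", cd$description %||% NA_character_)
  }))
  sch <- qca_schema(conds, doc$outcome$name,
                    outcome_calibrated = isTRUE(doc$outcome$calibrated),
                    raw_effect = doc$raw_effect)
  attr(sch, "delimiter") <- doc$delimiter
  sch
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a validated QCA data table
#'
#' @param cases A data frame with a `case_id` column, one numeric membership
#'   column per declared condition, the outcome column, and optionally the
#'   raw effect-size column.
#' @param schema A [qca_schema()].
#' @return An object of class `qca_data`: a list with elements `conditions`
#'   (the condition definitions), `outcome` (name + calibrated flag) and
#'   `cases` (the case data frame, columns reordered to case_id, conditions,
#'   raw effect, outcome).
#' @export
qca_data_table <- function(cases, schema) {
  stopifnot(inherits(schema, "qca_schema"), is.data.frame(cases))
  cases <- as.data.frame(cases, stringsAsFactors = FALSE)

  locate <- function(col) {
    hit <- which(tolower(names(cases)) == tolower(col))
    if (length(hit) != 1L) {
      stop(sprintf("schema error: column '%s' not found in data", col),
           call. = FALSE)
    }
    hit
  }
  id_col <- locate("case_id")
  cond_cols <- vapply(schema$conditions$name, locate, integer(1))
  out_col <- locate(schema$outcome$name)
  eff_col <- if (!is.null(schema$raw_effect)) locate(schema$raw_effect) else integer(0)

  ord <- c(id_col, cond_cols, eff_col, out_col)
  cases <- cases[, ord, drop = FALSE]
  names(cases) <- c("case_id", schema$conditions$name,
                    if (length(eff_col)) schema$raw_effect, schema$outcome$name)
  cases$case_id <- as.character(cases$case_id)
  rownames(cases) <- NULL

  x <- structure(list(conditions = schema$conditions,
                      outcome = schema$outcome,
                      raw_effect = schema$raw_effect,
                      cases = cases),
                 class = "qca_data")
  validate_qca_data(x)
}

#' @rdname qca_data_table
#' @param x A `qca_data` object.
#' @export
validate_qca_data <- function(x) {
  stopifnot(inherits(x, "qca_data"))
  cases <- x$cases
  if (nrow(cases) < 1L) stop("a data table needs at least one case", call. = FALSE)
  if (anyDuplicated(cases$case_id)) {
    stop("case_id values must be unique: ",
         paste(unique(cases$case_id[duplicated(cases$case_id)]), collapse = ", "),
         call. = FALSE)
  }
  mem_cols <- c(x$conditions$name,
                if (isTRUE(x$outcome$calibrated)) x$outcome$name)
  if (!isTRUE(x$outcome$calibrated)) {
    v <- cases[[x$outcome$name]]
    if (!is.numeric(v) || anyNA(v) || any(v <= 0)) {
      stop("uncalibrated outcome must hold positive odds ratios", call. = FALSE)
    }
  }
  for (col in mem_cols) {
    v <- cases[[col]]
    if (!is.numeric(v)) {
      stop(sprintf("column '%s' is not numeric", col), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing membership in column '%s' for case '%s'",
                   col, cases$case_id[which(is.na(v))[1]]), call. = FALSE)
    }
    bad <- which(v < 0 | v > 1)
    if (length(bad)) {
      stop(sprintf("membership outside [0,1] in column '%s' for case '%s' (value %g)",
                   col, cases$case_id[bad[1]], v[bad[1]]), call. = FALSE)
    }
  }
  for (i in seq_len(nrow(x$conditions))) {
    if (x$conditions$kind[i] == "crisp") {
      col <- x$conditions$name[i]
      v <- cases[[col]]
      bad <- which(!(v %in% c(0, 1)))
      if (length(bad)) {
        stop(sprintf("crisp condition '%s' has non-binary value %g for case '%s'",
                     col, v[bad[1]], cases$case_id[bad[1]]), call. = FALSE)
      }
    }
  }
  if (!is.null(x$raw_effect)) {
    v <- cases[[x$raw_effect]]
    if (!is.numeric(v) || any(is.na(v)) || any(v <= 0)) {
      stop("raw effect sizes must be positive odds ratios", call. = FALSE)
    }
  }
  x
}

#' @export
print.qca_data <- function(x, ...) {
  cat(sprintf("QCA data table: %d cases, %d conditions, outcome '%s'%s\n",
              nrow(x$cases), nrow(x$conditions), x$outcome$name,
              if (x$outcome$calibrated) " (calibrated)" else " (raw effect size)"))
  cat("Conditions:",
      paste(sprintf("%s [%s]", x$conditions$name, x$conditions$kind),
            collapse = ", "), "\n")
  print(x$cases, ...)
  invisible(x)
}

#' Condition names of a data table
#' @param x A `qca_data` object.
#' @return Character vector of declared condition names, in order.
#' @export
condition_names <- function(x) {
  stopifnot(inherits(x, "qca_data"))
  x$conditions$name
}

#' Membership matrix and outcome vector accessors
#'
#' `membership_matrix()` returns the cases-by-conditions numeric matrix;
#' `outcome_memberships()` the outcome membership vector (optionally
#' negated, i.e. `1 - y`). Both are row-named by `case_id`.
#'
#' @param x A `qca_data` object.
#' @param negated Return the fuzzy complement of the outcome?
#' @export
membership_matrix <- function(x) {
  stopifnot(inherits(x, "qca_data"))
  m <- as.matrix(x$cases[, x$conditions$name, drop = FALSE])
  rownames(m) <- x$cases$case_id
  m
}

#' @rdname membership_matrix
#' @export
outcome_memberships <- function(x, negated = FALSE) {
  stopifnot(inherits(x, "qca_data"))
  y <- x$cases[[x$outcome$name]]
  names(y) <- x$cases$case_id
  if (negated) 1 - y else y
}

# round-half-up at `digits` decimals; display convention for all reports
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

fmt_membership <- function(x, digits = 3) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a case-by-condition data table from delimited text
#'
#' Reads a comma- or tab-delimited file with a header row and validates it
#' against a schema. The dialect is auto-detected from the extension
#' (`.tsv` means tab, anything else comma) unless `delim` overrides it.
#'
#' @param path Path to the delimited file.
#' @param schema A [qca_schema()] (or the result of [read_schema()]).
#' @param delim Optional field delimiter overriding auto-detection.
#' @return A validated `qca_data` table; row order of the file is preserved.
#' @export
read_data_table <- function(path, schema, delim = NULL) {
  stopifnot(inherits(schema, "qca_schema"))
  delim <- delim_for(path, delim %||% attr(schema, "delimiter"))
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, quote = "\"",
                           stringsAsFactors = FALSE)
  num_cols <- c(schema$conditions$name, schema$raw_effect, schema$outcome$name)
  for (col in num_cols) {
    hit <- which(tolower(names(raw)) == tolower(col))
    if (length(hit) != 1L) {
      stop(sprintf("schema error: column '%s' not found in '%s'", col, path),
           call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(raw[[hit]]))
    bad <- which(is.na(v) & nzchar(raw[[hit]]))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric value '%s' in column '%s', row %d of '%s'",
                   raw[[hit]][bad[1]], names(raw)[hit], bad[1], path),
           call. = FALSE)
    }
    raw[[hit]] <- v
  }
  qca_data_table(raw, schema)
}

#' Write a data table as delimited text
#'
#' Columns are written in the canonical order (case_id, conditions in
#' declared order, raw effect size if present, outcome); memberships are
#' written with a fixed precision of three fractional digits, so that
#' [read_data_table()] of the written file reproduces the table exactly at
#' that precision.
#'
#' @param table A `qca_data` object.
#' @param path Output path; `.tsv` selects tab delimiting.
#' @param delim Optional delimiter override.
#' @export
write_data_table <- function(table, path, delim = NULL) {
  validate_qca_data(table)
  delim <- delim_for(path, delim)
  out <- table$cases
  for (col in c(table$conditions$name, table$outcome$name)) {
    out[[col]] <- fmt_membership(out[[col]])
  }
  if (!is.null(table$raw_effect)) {
    out[[table$raw_effect]] <- formatC(out[[table$raw_effect]],
                                       format = "f", digits = 3)
  }
  utils::write.table(out, path, sep = delim, quote = TRUE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
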