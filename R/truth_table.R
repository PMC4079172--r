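# Truth-table construction: assign cases to the 2^k corners, score fuzzy
# sufficiency consistency, classify rows, flag contradictions/remainders.

#' Assign a case to its truth-table corner
#'
#' A fuzzy case belongs to the corner it is more in than out of: per
#' condition, 1 if membership > 0.5 and 0 if < 0.5. A membership of exactly
#' 0.5 is undecidable (the crossover point belongs to neither side) and is
#' rejected — the calibration must be revisited.
#'
#' @param case Named numeric membership vector for one case (may carry a
#'   `case_id` attribute used in error messages).
#' @param conditions Character vector of selected condition names.
#' @return Named integer vector of 0/1 corner coordinates.
#' @export
assign_row <- function(case, conditions) {
  m <- case_matrix(case)
  vals <- vapply(conditions, function(cn) m[1, resolve_condition(cn, colnames(m))],
                 numeric(1))
  at_half <- which(vals == 0.5)
  if (length(at_half)) {
    id <- attr(case, "case_id") %||% rownames(m) %||% "<case>"
    stop(sprintf(paste0("cannot assign case '%s': membership in '%s' is exactly ",
                        "0.5 (crossover); revisit the calibration"),
                 id, conditions[at_half[1]]), call. = FALSE)
  }
  stats::setNames(as.integer(vals > 0.5), conditions)
}

corner_config <- function(corner, conditions) {
  qca_config(present = conditions[corner == 1L],
             absent = conditions[corner == 0L])
}

all_corners <- function(k) {
  # rows enumerate the 2^k corners; first condition is the most significant bit
  m <- as.matrix(expand.grid(rep(list(1:0), k))[, k:1, drop = FALSE])
  dimnames(m) <- NULL
  m[nrow(m):1, , drop = FALSE]
}

#' Fuzzy sufficiency consistency of a configuration
#'
#' The degree to which membership in the configuration is a subset of
#' membership in the outcome: `sum(min(x, y)) / sum(x)` over all cases,
#' where `x` is the configuration membership and `y` the (possibly
#' negated) outcome. For crisp `x` and `y` this reduces to the proportion
#' of the configuration's member cases that show the outcome.
#'
#' @param table A `qca_data` object with calibrated outcome.
#' @param config A `qca_config` (or single-term `qca_expr`).
#' @param outcome_negated Score against the negated outcome `1 - y`?
#' @return Consistency in \[0, 1\], or `NA_real_` when no case has any
#'   membership in the configuration (the configuration is a remainder and
#'   its consistency is undefined).
#' @export
raw_consistency <- function(table, config, outcome_negated = FALSE) {
  stopifnot(inherits(table, "qca_data"))
  if (inherits(config, "qca_expr")) {
    x <- expr_membership(table, config)
  } else {
    x <- config_membership(table, config)
  }
  y <- outcome_memberships(table, negated = outcome_negated)
  if (sum(x) == 0) return(NA_real_)
  sum(pmin(x, y)) / sum(x)
}

#' Does a truth-table row contain contradictory cases?
#'
#' A row is contradictory when its member cases disagree about the
#' (possibly negated) outcome: at least one member is more in than out of
#' the outcome set (> 0.5) and at least one is more out than in (< 0.5).
#' Graded memberships on the same side of the crossover are not
#' contradictions.
#'
#' @param member_outcomes Outcome memberships of the row's member cases, on
#'   the analysed (possibly negated) outcome; may be named by case id.
#' @return A list with `contradictory` (logical) and `explanation` (a
#'   string listing the member outcomes).
#' @export
detect_contradiction <- function(member_outcomes) {
  stopifnot(is.numeric(member_outcomes), length(member_outcomes) >= 1L)
  hi <- member_outcomes > 0.5
  lo <- member_outcomes < 0.5
  contradictory <- any(hi) && any(lo)
  labels <- if (is.null(names(member_outcomes))) {
    fmt_membership(member_outcomes)
  } else {
    paste0(names(member_outcomes), "=", fmt_membership(member_outcomes))
  }
  explanation <- if (contradictory) {
    sprintf("members disagree about the outcome: %s", paste(labels, collapse = ", "))
  } else {
    sprintf("member outcomes all on one side of 0.5: %s",
            paste(labels, collapse = ", "))
  }
  list(contradictory = contradictory, explanation = explanation)
}

#' Build the truth table for a set of conditions
#'
#' Enumerates all `2^k` corners of the selected conditions, assigns every
#' case to the corner it is more in than out of, computes each corner's
#' fuzzy sufficiency consistency over all cases, and classifies each row:
#' \describe{
#'   \item{remainder}{no case assigned (consistency undefined);}
#'   \item{positive}{consistency at or above `consistency_cutoff` and at
#'     least `frequency_cutoff` member cases;}
#'   \item{contradiction}{below the cutoff with member cases straddling the
#'     0.5 outcome crossover;}
#'   \item{negative}{otherwise.}
#' }
#' Straddling rows are additionally flagged in the `contradiction` column
#' whatever their class, so [resolve_contradictions()] and the
#' contradiction report see them even when they pass the cutoff.
#' Rows are ordered by descending consistency (ties by descending case
#' count, then corner), remainders last.
#'
#' @param table A `qca_data` object with calibrated outcome.
#' @param conditions Selected condition names (default: all declared).
#' @param consistency_cutoff Minimum raw consistency for a positive row
#'   (default 0.75).
#' @param frequency_cutoff Minimum number of member cases for a positive
#'   row (default 1: single-study rows enter minimisation).
#' @param outcome_negated Analyse the negated outcome `1 - y`?
#' @param max_k Hard cap on the number of conditions (default 8, i.e. 256
#'   rows).
#' @return A `qca_truth_table`: a data frame with one 0/1 column per
#'   condition plus `n_cases`, `case_ids` (comma-separated), `consistency`,
#'   `contradiction` and `outcome_class`; settings and the source table are
#'   attached as attributes.
#' @export
build_truth_table <- function(table, conditions = NULL,
                              consistency_cutoff = 0.75,
                              frequency_cutoff = 1,
                              outcome_negated = FALSE,
                              max_k = 8) {
  stopifnot(inherits(table, "qca_data"))
  if (!isTRUE(table$outcome$calibrated)) {
    stop("outcome must be calibrated before building a truth table", call. = FALSE)
  }
  conditions <- conditions %||% condition_names(table)
  conditions <- vapply(conditions, resolve_condition, character(1),
                       declared = condition_names(table))
  names(conditions) <- NULL
  k <- length(conditions)
  if (k < 1L || k > max_k) {
    stop(sprintf("number of conditions must be between 1 and %d", max_k),
         call. = FALSE)
  }
  if (!(consistency_cutoff > 0 && consistency_cutoff <= 1)) {
    stop("consistency cutoff must lie in (0, 1]", call. = FALSE)
  }

  m <- membership_matrix(table)[, conditions, drop = FALSE]
  y <- outcome_memberships(table, negated = outcome_negated)
  if (any(m == 0.5)) {
    bad <- which(m == 0.5, arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("cannot assign case '%s': membership in '%s' is exactly ",
                        "0.5 (crossover); revisit the calibration"),
                 rownames(m)[bad[1]], conditions[bad[2]]), call. = FALSE)
  }
  assigned <- (m > 0.5) * 1L
  corner_key <- apply(assigned, 1, paste, collapse = "")

  corners <- all_corners(k)
  colnames(corners) <- conditions
  keys <- apply(corners, 1, paste, collapse = "")

  rows <- data.frame(corners, check.names = FALSE)
  rows$n_cases <- 0L
  rows$case_ids <- ""
  rows$consistency <- NA_real_
  rows$contradiction <- FALSE
  rows$outcome_class <- "remainder"
  explanations <- stats::setNames(rep(NA_character_, nrow(rows)), keys)

  for (i in seq_len(nrow(rows))) {
    members <- names(corner_key)[corner_key == keys[i]]
    rows$n_cases[i] <- length(members)
    rows$case_ids[i] <- paste(members, collapse = "; ")
    cons <- raw_consistency(table, corner_config(corners[i, ], conditions),
                            outcome_negated = outcome_negated)
    rows$consistency[i] <- cons
    if (length(members) == 0L) next
    contra <- detect_contradiction(y[members])
    rows$contradiction[i] <- contra$contradictory
    explanations[i] <- contra$explanation
    rows$outcome_class[i] <-
      if (!is.na(cons) && cons >= consistency_cutoff &&
          length(members) >= frequency_cutoff) "positive"
      else if (contra$contradictory) "contradiction"
      else "negative"
  }

  remainder <- rows$outcome_class == "remainder"
  corner_value <- strtoi(keys, base = 2L)
  ord <- order(remainder, -ifelse(is.na(rows$consistency), -1, rows$consistency),
               -rows$n_cases, corner_value)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL

  structure(rows,
            class = c("qca_truth_table", "data.frame"),
            conditions = conditions,
            settings = list(consistency_cutoff = consistency_cutoff,
                            frequency_cutoff = frequency_cutoff,
                            outcome_negated = outcome_negated),
            explanations = explanations[ord],
            data = table)
}

tt_conditions <- function(tt) attr(tt, "conditions")
tt_settings <- function(tt) attr(tt, "settings")
tt_data <- function(tt) attr(tt, "data")

#' @export
print.qca_truth_table <- function(x, ...) {
  s <- tt_settings(x)
  cat(sprintf("Truth table: %d conditions (%s), %d rows, cutoff %.2f%s\n",
              length(tt_conditions(x)), paste(tt_conditions(x), collapse = ", "),
              nrow(x), s$consistency_cutoff,
              if (s$outcome_negated) ", negated outcome" else ""))
  disp <- as.data.frame(x)
  disp$case_ids <- NULL
  disp$consistency <- ifelse(is.na(disp$consistency), "",
                             fmt_membership(disp$consistency))
  print(disp, ...)
  invisible(x)
}

#' Resolve contradictory truth-table rows
#'
#' Computable resolution strategies for rows flagged contradictory:
#' \describe{
#'   \item{flag_only}{leave the classification as built (default);}
#'   \item{recode_zero}{recode contradictory rows as negative ("unclear");}
#'   \item{vote_count}{classify by majority vote of member cases with
#'     outcome above vs below 0.5; ties go to negative (no claim of
#'     sufficiency without a majority).}
#' }
#' Substantive resolutions (adding or replacing conditions, re-examining
#' the coding of source studies) are analyst actions; use
#' [quality_report()] and the contradiction explanations to drive them.
#'
#' @param truthtable A `qca_truth_table`.
#' @param strategy One of `"flag_only"`, `"recode_zero"`, `"vote_count"`.
#' @return The truth table with updated `outcome_class`.
#' @export
resolve_contradictions <- function(truthtable,
                                   strategy = c("flag_only", "recode_zero",
                                                "vote_count")) {
  stopifnot(inherits(truthtable, "qca_truth_table"))
  strategy <- match.arg(strategy)
  if (strategy == "flag_only") return(truthtable)
  flagged <- which(truthtable$contradiction)
  if (strategy == "recode_zero") {
    truthtable$outcome_class[flagged] <- "negative"
    return(truthtable)
  }
  table <- tt_data(truthtable)
  y <- outcome_memberships(table, negated = tt_settings(truthtable)$outcome_negated)
  for (i in flagged) {
    members <- strsplit(truthtable$case_ids[i], "; ", fixed = TRUE)[[1]]
    votes_for <- sum(y[members] > 0.5)
    votes_against <- sum(y[members] < 0.5)
    truthtable$outcome_class[i] <-
      if (votes_for > votes_against) "positive" else "negative"
  }
  truthtable
}

#' Truth-table quality diagnostics
#'
#' Summarises the spread of cases over configurations: counts of rows by
#' class, the number and fraction of remainders (limited diversity),
#' whether both positive and negative rows exist, and the maximum row
#' occupancy. Warnings are issued (as report entries, not R warnings) when
#' remainders exceed `remainder_warn_fraction` of the rows — the analysis
#' risks becoming a description of individual studies — and when at most
#' one row passes the consistency cutoff.
#'
#' @param truthtable A `qca_truth_table`.
#' @param remainder_warn_fraction Limited-diversity warning threshold
#'   (default 0.5).
#' @return A list of class `qca_quality` with elements `n_rows`,
#'   `class_counts`, `n_remainders`, `remainder_fraction`,
#'   `has_positive`, `has_negative`, `max_row_occupancy`, `warnings`.
#' @export
quality_report <- function(truthtable, remainder_warn_fraction = 0.5) {
  stopifnot(inherits(truthtable, "qca_truth_table"))
  cls <- truthtable$outcome_class
  counts <- vapply(c("positive", "negative", "contradiction", "remainder"),
                   function(cc) sum(cls == cc), integer(1))
  n_rem <- counts[["remainder"]]
  frac <- n_rem / nrow(truthtable)
  warnings <- character(0)
  if (frac > remainder_warn_fraction) {
    warnings <- c(warnings, sprintf(
      "limited diversity: %d of %d configurations have no cases (%.0f%%)",
      n_rem, nrow(truthtable), 100 * frac))
  }
  if (counts[["positive"]] <= 1L) {
    warnings <- c(warnings, sprintf(
      "only %d row(s) pass the consistency cutoff %.2f",
      counts[["positive"]], tt_settings(truthtable)$consistency_cutoff))
  }
  n_flagged <- sum(truthtable$contradiction)
  if (n_flagged > 0L) {
    warnings <- c(warnings, sprintf(
      "%d contradictory configuration(s) need resolution before minimisation",
      n_flagged))
  }
  structure(list(n_rows = nrow(truthtable),
                 class_counts = as.list(counts),
                 n_remainders = n_rem,
                 remainder_fraction = frac,
                 has_positive = counts[["positive"]] > 0L,
                 has_negative = counts[["negative"]] > 0L,
                 max_row_occupancy = max(truthtable$n_cases),
                 warnings = warnings),
            class = "qca_quality")
}

#' @export
print.qca_quality <- function(x, ...) {
  cat(sprintf("Truth-table quality: %d rows (%d positive, %d negative, %d contradictory, %d remainders)\n",
              x$n_rows, x$class_counts$positive, x$class_counts$negative,
              x$class_counts$contradiction, x$n_remainders))
  cat(sprintf("Remainder fraction %.2f; max row occupancy %d\n",
              x$remainder_fraction, x$max_row_occupancy))
  for (w in x$warnings) cat("Warning:", w, "\n")
  invisible(x)
}

#' Export a truth table as delimited text
#'
#' One column per condition, then the number of cases, the outcome class,
#' and the raw consistency at three decimals; remainder rows come last with
#' a blank consistency cell.
#'
#' @param truthtable A `qca_truth_table`.
#' @param path Output path; `.tsv` selects tab delimiting.
#' @param delim Optional delimiter override.
#' @export
write_truth_table <- function(truthtable, path, delim = NULL) {
  stopifnot(inherits(truthtable, "qca_truth_table"))
  delim <- delim_for(path, delim)
  out <- as.data.frame(truthtable)[, c(tt_conditions(truthtable), "n_cases",
                                       "outcome_class", "consistency")]
  out$consistency <- ifelse(is.na(out$consistency), "",
                            fmt_membership(out$consistency))
  utils::write.table(out, path, sep = delim, quote = TRUE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
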