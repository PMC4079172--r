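# Shared fixtures and independent oracles for the test suite.

bf_table <- load_breastfeeding()

# tiny hand-built table: one fuzzy condition, one crisp condition
tiny_table <- function() {
  schema <- qca_schema(c(A = "crisp", B = "fuzzy"), "Y")
  qca_data_table(
    data.frame(case_id = c("s1", "s2", "s3"),
               A = c(1, 0, 1), B = c(0.666, 0.333, 1), Y = c(1, 0, 0.666)),
    schema)
}

# find a truth-table row by its corner coordinates
tt_row <- function(tt, ...) {
  corner <- c(...)
  rows <- as.data.frame(tt)
  hit <- rep(TRUE, nrow(rows))
  for (nm in names(corner)) hit <- hit & rows[[nm]] == corner[[nm]]
  stopifnot(sum(hit) == 1L)
  rows[hit, , drop = FALSE]
}

# independent interval-scan oracle for the default calibration rules:
# walks the printed inequalities directly
calibration_oracle <- function(or) {
  lor <- log(or)
  if (lor > 0.7) 1
  else if (lor > 0.4) 0.666
  else if (lor > 0) 0.333
  else 0
}

# counting oracle for crisp-set sufficiency consistency:
# members of the corner with outcome 1, over all members
crisp_consistency_oracle <- function(m, y, corner) {
  member <- apply(m, 1, function(r) all(r == corner))
  if (!any(member)) return(NA_real_)
  sum(y[member] == 1) / sum(member)
}

# evaluate an expression on every 0/1 corner of the given conditions
expr_truth_vector <- function(expr, conditions) {
  corners <- qcasynth:::all_corners(length(conditions))
  colnames(corners) <- conditions
  as.numeric(expr_membership(corners, expr))
}

# exhaustive minimal-cover oracle: smallest subset of primes covering all
# minterms, then fewest literals
exhaustive_cover_oracle <- function(primes, minterm_strings) {
  covers_mt <- function(p, mt) {
    pc <- strsplit(p, "")[[1]]; mc <- strsplit(mt, "")[[1]]
    all(pc == "-" | pc == mc)
  }
  best <- NULL; best_cost <- c(Inf, Inf)
  for (size in seq_along(primes)) {
    for (sel in utils::combn(primes, size, simplify = FALSE)) {
      ok <- all(vapply(minterm_strings, function(mt)
        any(vapply(sel, covers_mt, logical(1), mt = mt)), logical(1)))
      if (ok) {
        lits <- sum(vapply(sel, function(p)
          sum(strsplit(p, "")[[1]] != "-"), numeric(1)))
        if (size < best_cost[1] ||
            (size == best_cost[1] && lits < best_cost[2])) {
          best <- sel; best_cost <- c(size, lits)
        }
      }
    }
    if (!is.null(best)) break
  }
  list(size = best_cost[1], literals = best_cost[2], cover = best)
}

# draw a random positive/remainder corner split over k conditions
random_corner_split <- function(k, with_remainders = TRUE) {
  corners <- qcasynth:::all_corners(k)
  n <- nrow(corners)
  n_pos <- sample(seq_len(n - 1), 1)
  idx <- sample(seq_len(n), n_pos)
  rest <- setdiff(seq_len(n), idx)
  n_rem <- if (with_remainders && length(rest) > 1) {
    sample(0:(length(rest) - 1), 1)
  } else 0
  rem_idx <- if (n_rem > 0) sample(rest, n_rem) else integer(0)
  conds <- LETTERS[seq_len(k)]
  pos <- corners[idx, , drop = FALSE]; colnames(pos) <- conds
  rem <- corners[rem_idx, , drop = FALSE]; colnames(rem) <- conds
  list(conditions = conds, positive = pos, remainder = rem,
       negative = corners[setdiff(rest, rem_idx), , drop = FALSE])
}
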