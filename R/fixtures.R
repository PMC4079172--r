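# Bundled worked-example data set and a synthetic study-set generator with
# known configurational structure.

#' The breastfeeding-intervention worked example
#'
#' Twelve controlled trials of breastfeeding-promotion interventions that
#' incorporate community engagement, coded on five conditions (crisp:
#' Empowerment, Design, Lay-led; fuzzy: Quality, Intensity) with the raw
#' effect size (odds ratio) and the published fuzzy membership in the set
#' of highly effective interventions.
#'
#' The fuzzy outcome column is stored verbatim as published, not re-derived
#' from the raw odds ratios: four of the twelve rows do not reproduce under
#' the stated calibration scheme in any log base, consistent with the
#' published effect sizes having been cluster-adjusted before calibration
#' without the adjusted values being reported. Downstream quantities depend
#' on the published memberships, so those are authoritative here.
#'
#' @return A `qca_data` table with 12 cases, 5 conditions and one
#'   calibrated outcome.
#' @seealso [breastfeeding_errata()] for documented discrepancies between
#'   the published data table and the published analysis tables.
#' @export
load_breastfeeding <- function() {
  schema <- read_schema(system.file("extdata", "breastfeeding.yaml",
                                    package = "qcasynth", mustWork = TRUE))
  read_data_table(system.file("extdata", "breastfeeding.csv",
                              package = "qcasynth", mustWork = TRUE),
                  schema)
}

#' Documented discrepancies in the worked example
#'
#' Several published truth-table consistencies and solution metrics are not
#' reproducible from the published case memberships under any standard
#' consistency formula (the pattern suggests some outcome memberships were
#' revised between the data table and the analyses). This table records
#' each published value next to the value recomputed from the published
#' memberships, with a note on the arithmetic. The package's tests assert
#' the recomputed values.
#'
#' @return A data frame with columns `quantity`, `printed`, `recomputed`,
#'   `note`.
#' @export
breastfeeding_errata <- function() {
  utils::read.csv(system.file("extdata", "breastfeeding_errata.csv",
                              package = "qcasynth", mustWork = TRUE),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' Specify a synthetic study set
#'
#' Describes a study set generated from a known sufficient-condition
#' structure: `n` cases over `k` conditions, with the outcome equal to the
#' case's membership in a generating DNF expression, optionally perturbed.
#'
#' @param k Number of conditions (>= 1).
#' @param n Number of cases (>= 1).
#' @param true_dnf The generating expression: a label string (parsed
#'   against `conditions`) or a `qca_expr`.
#' @param consistency_noise Probability in \[0, 1) of flipping a generated
#'   outcome to the opposite side of the 0.5 crossover (`y -> 1 - y`).
#' @param fuzziness Probability of replacing a crisp membership with the
#'   graded level on the same side of the crossover (1 -> 0.666,
#'   0 -> 0.333).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param conditions Condition names (default `LETTERS[1:k]`).
#' @param ensure_corners Lay down all `2^k` corners as the first cases
#'   (requires `n >= 2^k`); used for recovery testing where every
#'   configuration must be observed.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(k, n, true_dnf, consistency_noise = 0,
                           fuzziness = 0, seed = 1L,
                           conditions = LETTERS[seq_len(k)],
                           ensure_corners = FALSE) {
  stopifnot(k >= 1, length(conditions) == k)
  if (n < 1) stop("a generated study set needs at least one case", call. = FALSE)
  if (consistency_noise < 0 || consistency_noise >= 1) {
    stop("consistency_noise must lie in [0, 1)", call. = FALSE)
  }
  if (fuzziness < 0 || fuzziness > 1) {
    stop("fuzziness must lie in [0, 1]", call. = FALSE)
  }
  if (ensure_corners && n < 2^k) {
    stop("ensure_corners requires n >= 2^k", call. = FALSE)
  }
  if (is.character(true_dnf)) true_dnf <- parse_label(true_dnf, conditions)
  stopifnot(inherits(true_dnf, "qca_expr"))
  for (tm in true_dnf) {
    vapply(names(tm), resolve_condition, character(1), declared = conditions)
  }
  structure(list(k = k, n = n, true_dnf = true_dnf,
                 consistency_noise = consistency_noise,
                 fuzziness = fuzziness, seed = as.integer(seed),
                 conditions = conditions, ensure_corners = ensure_corners),
            class = "generator_spec")
}

#' Generate a synthetic study set
#'
#' Condition corner bits are drawn independently Bernoulli(0.5) (after the
#' optional full corner enumeration); with probability `fuzziness` a bit is
#' displayed as the graded membership on the same side of 0.5. The outcome
#' is the case's fuzzy membership in the generating DNF, flipped across the
#' crossover with probability `consistency_noise`. The generating
#' expression is attached as the `"true_dnf"` attribute.
#'
#' @param spec A [generator_spec()].
#' @return A `qca_data` table with `n` cases and `k` conditions.
#' @export
generate_studies <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  k <- spec$k; n <- spec$n
  bits <- matrix(stats::rbinom(n * k, 1L, 0.5), nrow = n, ncol = k)
  if (spec$ensure_corners) {
    bits[seq_len(2^k), ] <- all_corners(k)
  }
  colnames(bits) <- spec$conditions

  mem <- bits
  if (spec$fuzziness > 0) {
    grade <- matrix(stats::runif(n * k) < spec$fuzziness, nrow = n)
    mem <- ifelse(grade, ifelse(bits == 1L, 0.666, 0.333), bits)
    colnames(mem) <- spec$conditions
  }

  y <- expr_membership(mem, spec$true_dnf)
  if (spec$consistency_noise > 0) {
    flip <- stats::runif(n) < spec$consistency_noise
    y[flip] <- 1 - y[flip]
  }

  cases <- data.frame(case_id = sprintf("S%03d", seq_len(n)),
                      mem, Outcome = as.numeric(y),
                      check.names = FALSE, stringsAsFactors = FALSE)
  kind <- if (spec$fuzziness > 0) "fuzzy" else "crisp"
  schema <- qca_schema(stats::setNames(rep(kind, k), spec$conditions), "Outcome")
  out <- qca_data_table(cases, schema)
  attr(out, "true_dnf") <- spec$true_dnf
  out
}
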