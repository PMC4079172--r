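test_that("the worked example's three positive rows minimise to two terms", {
  pos <- rbind(c(1, 0), c(1, 1), c(0, 1))
  colnames(pos) <- c("Intensity", "Quality")
  sol <- minimise(pos)
  expect_equal(format_label(sol$expression, c("Intensity", "Quality")),
               "Intensity + Quality")
  expect_equal(sol$policy, "conservative")
})

test_that("degenerate minterm sets minimise to the expected implicants", {
  # all corners -> universal expression
  allc <- qcasynth:::all_corners(2)
  colnames(allc) <- c("A", "B")
  expect_equal(format_label(minimise(allc)$expression), "1")
  # a single positive corner is its own (only) implicant
  one <- matrix(c(0, 1, 1), nrow = 1,
                dimnames = list(NULL, c("Empowerment", "Design", "Lay-led")))
  expect_equal(format_label(minimise(one)$expression,
                            c("Empowerment", "Design", "Lay-led")),
               "~Empowerment*Design*Lay-led")
  expect_error(minimise(matrix(numeric(0), ncol = 2)), "nothing to minimise")
})

test_that("prime implicants are the maximal merged cubes", {
  mts <- rbind(c(1, 0), c(1, 1), c(0, 1))
  expect_equal(sort(prime_implicants(mts)), c("-1", "1-"))
  expect_equal(prime_implicants(matrix(c(1, 0, 1), nrow = 1)), "101")
  full <- qcasynth:::all_corners(2)
  expect_equal(prime_implicants(full), "--")
})

test_that("cover selection keeps essential primes and solves the rest exactly", {
  mts <- rbind(c(1, 0), c(1, 1), c(0, 1))
  expect_setequal(select_cover(c("1-", "-1"), mts), c("1-", "-1"))
  expect_equal(select_cover("---", qcasynth:::all_corners(3)), "---")

  # cyclic chart on 3 variables: six minterms, six primes, no essentials
  cyc <- rbind(c(0, 0, 1), c(0, 1, 1), c(0, 1, 0), c(1, 1, 0),
               c(1, 0, 0), c(1, 0, 1))
  primes <- prime_implicants(cyc)
  expect_length(primes, 6L)
  chosen <- select_cover(primes, cyc)
  oracle <- exhaustive_cover_oracle(primes, apply(cyc, 1, paste, collapse = ""))
  expect_equal(length(chosen), oracle$size)
  expect_equal(sum(vapply(chosen, function(p)
    sum(strsplit(p, "")[[1]] != "-"), numeric(1))), oracle$literals)
})

test_that("conservative solutions are logically equivalent to their inputs", {
  set.seed(37)
  for (i in 1:60) {
    k <- sample(2:5, 1)
    split <- random_corner_split(k, with_remainders = FALSE)
    sol <- minimise(split$positive, conditions = split$conditions)
    truth <- expr_truth_vector(sol$expression, split$conditions)
    corners <- qcasynth:::all_corners(k)
    want <- as.numeric(apply(corners, 1, paste, collapse = "") %in%
                         apply(split$positive, 1, paste, collapse = ""))
    expect_equal(truth, want)
  }
})

test_that("parsimonious solutions respect don't-cares and never grow", {
  set.seed(43)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    split <- random_corner_split(k, with_remainders = TRUE)
    cons <- minimise(split$positive, split$remainder,
                     conditions = split$conditions, policy = "conservative")
    pars <- minimise(split$positive, split$remainder,
                     conditions = split$conditions, policy = "parsimonious")
    expect_lte(length(pars$expression), length(cons$expression))
    truth <- expr_truth_vector(pars$expression, split$conditions)
    keys <- apply(qcasynth:::all_corners(k), 1, paste, collapse = "")
    pos_keys <- apply(split$positive, 1, paste, collapse = "")
    neg_keys <- if (nrow(split$negative)) {
      apply(split$negative, 1, paste, collapse = "")
    } else character(0)
    expect_true(all(truth[keys %in% pos_keys] == 1))
    expect_true(all(truth[keys %in% neg_keys] == 0))
  }
})

test_that("minimisation is deterministic and validates its inputs", {
  set.seed(47)
  split <- random_corner_split(4)
  a <- minimise(split$positive, split$remainder, conditions = split$conditions)
  b <- minimise(split$positive, split$remainder, conditions = split$conditions)
  expect_identical(a$implicants, b$implicants)
  expect_identical(format_label(a$expression, split$conditions),
                   format_label(b$expression, split$conditions))
  overlap <- rbind(split$positive[1, ])
  colnames(overlap) <- split$conditions
  expect_error(minimise(split$positive, overlap,
                        conditions = split$conditions), "disjoint")
})

test_that("minimise_truth_table wires positives, remainders and metrics", {
  tt <- build_truth_table(bf_table, c("Intensity", "Quality"))
  sol <- minimise_truth_table(tt)
  expect_equal(format_label(sol$expression, sol$conditions), "Intensity")
  expect_equal(round(sol$metrics$solution_coverage, 3), 0.560)
  expect_equal(round(sol$metrics$solution_consistency, 3), 0.933)

  tt1 <- build_truth_table(bf_table, c("Empowerment", "Design", "Lay-led"),
                           outcome_negated = TRUE)
  sol1 <- minimise_truth_table(tt1)
  expect_equal(format_label(sol1$expression, sol1$conditions),
               "~Empowerment*Design*~Lay-led")
})
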