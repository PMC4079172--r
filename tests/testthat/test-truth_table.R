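test_that("fuzzy cases are assigned to the corner they are more in than out of", {
  cau <- c(Quality = 0.333, Intensity = 1)
  expect_equal(assign_row(cau, c("Intensity", "Quality")),
               c(Intensity = 1L, Quality = 0L))
  crisp <- c(A = 1, B = 0)
  expect_equal(assign_row(crisp, c("A", "B")), c(A = 1L, B = 0L))
  expect_error(assign_row(c(A = 0.5), "A"), "exactly\\s*0.5")
})

test_that("raw consistency reproduces the worked example's sufficiency scores", {
  iq <- qca_config(present = c("Intensity", "Quality"))
  # sum(min(x,y)) = 1 + 0.333 + 1 + 0.666 + 1 over sum(x) = 4.333
  expect_equal(round(raw_consistency(bf_table, iq), 3), 0.923)

  schafer_row <- qca_config(present = c("Design", "Lay-led"),
                            absent = "Empowerment")
  expect_equal(raw_consistency(bf_table, schafer_row), 1.000)

  mcinnes_row <- qca_config(present = c("Empowerment", "Design", "Lay-led"))
  expect_equal(round(raw_consistency(bf_table, mcinnes_row), 3), 0.333)
  expect_equal(round(raw_consistency(bf_table, mcinnes_row,
                                     outcome_negated = TRUE), 3), 0.667)

  # recomputed from the published case memberships: (1+1+1+0.333+0.666)/5
  lay_row <- qca_config(present = "Lay-led",
                        absent = c("Empowerment", "Design"))
  expect_equal(round(raw_consistency(bf_table, lay_row), 3), 0.800)

  # no membership anywhere signals a remainder, not a number
  empty_cfg <- parse_label("Empowerment*~Design*~Lay-led*~Quality*~Intensity",
                           bf_table)[[1]]
  expect_true(is.na(raw_consistency(bf_table, empty_cfg)))
})

test_that("model 3 truth table has the published structure", {
  tt <- build_truth_table(bf_table, c("Intensity", "Quality"))
  expect_equal(nrow(tt), 4L)
  expect_equal(sum(tt$n_cases), 12L)
  expect_equal(tt_row(tt, Intensity = 1, Quality = 0)$n_cases, 1L)
  expect_equal(tt_row(tt, Intensity = 1, Quality = 1)$n_cases, 4L)
  expect_equal(tt_row(tt, Intensity = 0, Quality = 1)$n_cases, 1L)
  expect_equal(tt_row(tt, Intensity = 0, Quality = 0)$n_cases, 6L)
  expect_equal(tt_row(tt, Intensity = 1, Quality = 0)$consistency, 1.000)
  expect_equal(round(tt_row(tt, Intensity = 1, Quality = 1)$consistency, 3),
               0.923)
  # Caulfield sits in corner (1,0) though it contributes 0.333 to I*Q
  expect_match(tt_row(tt, Intensity = 1, Quality = 0)$case_ids, "Caulfield")
  expect_equal(tt_row(tt, Intensity = 1, Quality = 0)$outcome_class, "positive")
  expect_equal(tt_row(tt, Intensity = 1, Quality = 1)$outcome_class, "positive")
  # rows sorted by descending consistency, remainders (none here) last
  expect_equal(order(tt$consistency, decreasing = TRUE), seq_len(4))
})

test_that("model 1 truth table flags its remainders and contradictions", {
  conds <- c("Empowerment", "Design", "Lay-led")
  tt <- build_truth_table(bf_table, conds)
  expect_equal(nrow(tt), 8L)
  rem <- as.data.frame(tt)[tt$outcome_class == "remainder", conds]
  expect_equal(nrow(rem), 2L)
  expect_true(all(rem$Empowerment == 1 & rem$Design == 0))
  expect_setequal(rem$`Lay-led`, c(0, 1))
  # remainders sort last with undefined consistency
  expect_true(all(is.na(tt$consistency[7:8])))

  expect_equal(tt_row(tt, Empowerment = 0, Design = 0, `Lay-led` = 1)$n_cases, 5L)
  r011 <- tt_row(tt, Empowerment = 0, Design = 1, `Lay-led` = 1)
  expect_equal(r011$consistency, 1.000)
  expect_equal(r011$outcome_class, "positive")
  # the five-study row mixes full members with a 0.333 member: flagged
  # contradictory even though its recomputed consistency clears the cutoff
  r001 <- tt_row(tt, Empowerment = 0, Design = 0, `Lay-led` = 1)
  expect_true(r001$contradiction)
  expect_equal(r001$outcome_class, "positive")
})

test_that("the negated-outcome model passes exactly one row", {
  conds <- c("Empowerment", "Design", "Lay-led")
  tt <- build_truth_table(bf_table, conds, outcome_negated = TRUE)
  pos <- as.data.frame(tt)[tt$outcome_class == "positive", conds]
  expect_equal(nrow(pos), 1L)
  expect_equal(unlist(pos), c(Empowerment = 0, Design = 1, `Lay-led` = 0))
  expect_equal(round(tt_row(tt, Empowerment = 1, Design = 1,
                            `Lay-led` = 1)$consistency, 3), 0.667)
})

test_that("contradiction detection follows the 0.5 crossover rule", {
  # the worked example's (1,1) row: 0.666 is on the same side as the 1s
  expect_false(detect_contradiction(c(1, 1, 0.666, 1))$contradictory)
  expect_true(detect_contradiction(c(1, 0))$contradictory)
  expect_false(detect_contradiction(c(0.666))$contradictory)
  out <- detect_contradiction(c(a = 1, b = 0))
  expect_match(out$explanation, "a=1.000")
  expect_match(out$explanation, "disagree")
})

test_that("contradiction strategies recode as documented", {
  schema <- qca_schema(c(A = "crisp"), "Y")
  tab <- qca_data_table(
    data.frame(case_id = paste0("s", 1:5), A = c(1, 1, 1, 0, 0),
               Y = c(1, 1, 0, 1, 0)), schema)
  tt <- build_truth_table(tab, "A")
  expect_equal(sort(tt$outcome_class), c("contradiction", "contradiction"))

  recoded <- resolve_contradictions(tt, "recode_zero")
  expect_true(all(recoded$outcome_class == "negative"))
  expect_true(all(recoded$contradiction))  # the flag itself stays

  voted <- resolve_contradictions(tt, "vote_count")
  expect_equal(tt_row(voted, A = 1)$outcome_class, "positive")  # {1,1,0}
  expect_equal(tt_row(voted, A = 0)$outcome_class, "negative")  # tie {1,0}

  expect_identical(resolve_contradictions(tt, "flag_only"), tt)
})

test_that("quality diagnostics summarise spread, remainders and warnings", {
  tt1 <- build_truth_table(bf_table, c("Empowerment", "Design", "Lay-led"))
  q1 <- quality_report(tt1)
  expect_equal(q1$n_remainders, 2L)
  expect_equal(q1$remainder_fraction, 0.25)
  expect_equal(q1$max_row_occupancy, 5L)
  expect_true(any(grepl("contradictory", q1$warnings)))

  tt3 <- build_truth_table(bf_table, c("Intensity", "Quality"))
  expect_equal(quality_report(tt3)$n_remainders, 0L)

  # fully populated one-condition table with clean classes: no warnings
  schema <- qca_schema(c(A = "crisp"), "Y")
  tab <- qca_data_table(
    data.frame(case_id = paste0("s", 1:4), A = c(1, 1, 0, 0),
               Y = c(1, 1, 0, 0)), schema)
  q <- quality_report(build_truth_table(tab, "A"))
  expect_equal(q$n_remainders, 0L)
  expect_true(q$has_positive && q$has_negative)
  expect_length(setdiff(q$warnings, character(0)), 1L)  # only one positive row
})

test_that("one crisp case over one condition yields a remainder row", {
  schema <- qca_schema(c(A = "crisp"), "Y")
  tab <- qca_data_table(data.frame(case_id = "s1", A = 1, Y = 1), schema)
  tt <- build_truth_table(tab, "A")
  expect_equal(nrow(tt), 2L)
  expect_equal(sum(tt$outcome_class == "remainder"), 1L)
})

test_that("case counts always partition the cases (random tables)", {
  set.seed(29)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    spec <- generator_spec(k, n = sample(5:30, 1), true_dnf = "A",
                           consistency_noise = 0.2, fuzziness = 0.4,
                           seed = 100 + i)
    tab <- generate_studies(spec)
    tt <- build_truth_table(tab)
    expect_equal(sum(tt$n_cases), nrow(tab$cases))
    ids <- unlist(strsplit(tt$case_ids[tt$case_ids != ""], "; "))
    expect_setequal(ids, tab$cases$case_id)
  }
})

test_that("crisp consistency equals the counting formula (random tables)", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    spec <- generator_spec(k, n = sample(8:30, 1), true_dnf = "A",
                           consistency_noise = 0.3, fuzziness = 0,
                           seed = 200 + i)
    tab <- generate_studies(spec)
    tt <- build_truth_table(tab)
    m <- membership_matrix(tab)[, attr(tt, "conditions"), drop = FALSE]
    y <- outcome_memberships(tab)
    for (r in which(tt$n_cases > 0)) {
      corner <- unlist(as.data.frame(tt)[r, attr(tt, "conditions")])
      expect_equal(tt$consistency[r], crisp_consistency_oracle(m, y, corner))
    }
  }
})

test_that("plain and negated consistencies sum to 1 for crisp configurations", {
  conds <- c("Empowerment", "Design", "Lay-led")  # all crisp in the fixture
  tt <- build_truth_table(bf_table, conds)
  for (r in which(tt$n_cases > 0)) {
    corner_df <- as.data.frame(tt)[r, conds]
    cfg <- qca_config(present = conds[unlist(corner_df) == 1],
                      absent = conds[unlist(corner_df) == 0])
    expect_equal(raw_consistency(bf_table, cfg) +
                   raw_consistency(bf_table, cfg, outcome_negated = TRUE), 1)
  }
})

test_that("the exported truth table uses the standard layout", {
  tt <- build_truth_table(bf_table, c("Empowerment", "Design", "Lay-led"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth_table(tt, path)
  out <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  expect_equal(names(out), c("Empowerment", "Design", "Lay-led", "n_cases",
                             "outcome_class", "consistency"))
  # remainders last with blank consistency, three-decimal display elsewhere
  expect_equal(out$consistency[7:8], c("", ""))
  expect_equal(out$consistency[1], "1.000")
  expect_true("0.800" %in% out$consistency)
})
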