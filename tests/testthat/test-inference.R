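test_that("BMI computation and threshold comparison behave as specified", {
  expect_equal(compute_bmi(70, 175), 70 / 1.75^2)
  expect_equal(compute_bmi(100, 100), 100)
  expect_error(compute_bmi(80, 0), "height")
  expect_error(compute_bmi(-1, 170), "weight")

  expect_true(bmi_elevated(26, 25))
  expect_true(bmi_elevated(25, 25))   # inclusive boundary
  expect_false(bmi_elevated(20, 25))
})

test_that("group evaluation is tri-state, polarity-aware and short-circuiting", {
  kb <- kb_fixture()

  # fracture case study: all six contraindication questions answered No
  f <- evaluate_group(kb, case_fracture(), "G1")
  expect_identical(f$state, "absent")

  # sprain case study: G2 all answered, balance question Yes -> no positive
  # Ottawa finding (the positive finding is the inability to bear weight)
  f <- evaluate_group(kb, case_sprain(), "G2")
  expect_identical(f$state, "absent")

  # one positive answer decides the group despite unanswered questions
  a <- answer_set(c("G3-A.Q1" = "yes"))
  f <- evaluate_group(kb, a, "G3-A")
  expect_identical(f$state, "positive-present")
  expect_identical(f$positive_questions, "G3-A.Q1")

  # all-negative but incomplete stays undetermined
  a <- answer_set(c("G3-A.Q1" = "no"))
  expect_identical(evaluate_group(kb, a, "G3-A")$state, "undetermined")

  # body metrics feed the thresholded question
  a <- answer_set(c("G3-B.Q4" = "no", "G3-B.Q5" = "no", "G3-B.Q6" = "no",
                    "G3-B.Q7" = "no", "G3-B.Q9" = "no"),
                  weight_kg = 100, height_cm = 170)
  expect_identical(evaluate_group(kb, a, "G3-B")$state, "positive-present")
  a$weight_kg <- 60
  expect_identical(evaluate_group(kb, a, "G3-B")$state, "absent")

  # female-only question auto-resolves for non-female patients
  a <- answer_set(c(G1.Q1 = "no", G1.Q2 = "no", G1.Q3 = "no",
                    G1.Q5 = "no", G1.Q6 = "no"), sex = "male")
  expect_identical(evaluate_group(kb, a, "G1")$state, "absent")
  a$sex <- "female"
  expect_identical(evaluate_group(kb, a, "G1")$state, "undetermined")

  expect_error(evaluate_group(kb, answer_set(), "G7"), "unknown group")
})

test_that("condition evaluation follows strong Kleene three-valued logic", {
  kb <- kb_fixture()

  # no-injury case 1 is true when its three groups are all absent
  cond <- kb$rules[["3"]]$cases[[1]]$condition
  ev <- evaluate_condition(cond, c(G1 = "absent", G2 = "absent",
                                   "G4-A" = "absent"))
  expect_true(ev$value)

  and2 <- cnd_and(any_positive("A"), any_positive("B"))
  or2 <- cnd_or(any_positive("A"), any_positive("B"))
  expect_true(is.na(evaluate_condition(and2, c(A = TRUE, B = NA))$value))
  expect_true(evaluate_condition(or2, c(A = TRUE, B = NA))$value)
  expect_false(evaluate_condition(and2, c(A = FALSE, B = NA))$value)
  expect_true(is.na(evaluate_condition(or2, c(A = FALSE, B = NA))$value))

  # none_positive is the Kleene negation of any_positive
  expect_true(is.na(evaluate_condition(none_positive("A"), c(A = NA))$value))
  expect_false(evaluate_condition(none_positive("A"), c(A = TRUE))$value)

  expect_error(evaluate_condition(and2, c(A = TRUE)), "no finding")
})

test_that("case-study patients classify as published", {
  kb <- kb_fixture()
  p1 <- case_fracture()
  for (mode in c("strict", "compatibility")) {
    cls <- classify(kb, p1, mode = mode)
    expect_identical(cls$status, "determined")
    expect_equal(cls$rule_id, 1L)
    expect_equal(cls$case_index, 1L)
    expect_identical(cls$outcome_label, "High possibility of ankle fracture")
    expect_identical(cls$mode, mode)
  }

  p2 <- case_sprain()
  compat <- classify(kb, p2, mode = "compatibility")
  expect_equal(c(compat$rule_id, compat$case_index), c(2L, 1L))
  expect_identical(compat$outcome_label, "High possibility of ankle sprain")
  expect_length(compat$red_flags, 1L)

  strict <- classify(kb, p2, mode = "strict")
  expect_equal(c(strict$rule_id, strict$case_index), c(1L, 2L))
  expect_identical(strict$outcome_label, "High possibility of ankle fracture")
})

test_that("a complete all-negative questionnaire yields no injury", {
  kb <- kb_fixture()
  cls <- classify(kb, all_negative_answers(kb))
  expect_identical(cls$status, "determined")
  expect_equal(c(cls$rule_id, cls$case_index), c(3L, 1L))
  expect_identical(cls$outcome_label, "The patient does not have an injury")
})

test_that("classification is deterministic including its trace", {
  kb <- kb_fixture()
  a <- random_partial_answers(kb)
  expect_identical(classify(kb, a), classify(kb, a))
})

test_that("a partial answer set blocked by an unknown higher-priority case is not determined", {
  kb <- kb_fixture()
  # G4-A positive (sprain candidate) but G1 entirely unanswered: the sprain
  # case may be true in some completions, the fracture cases in others
  a <- answer_set(c("G4-A.Q1" = "yes"))
  cls <- classify(kb, a)
  expect_identical(cls$status, "needs-more-answers")
  expect_true("G1" %in% cls$blocking$group)
})

test_that("determined classifications are final under any completion", {
  kb <- kb_fixture()
  set.seed(42)
  checked <- 0L
  for (i in 1:200) {
    a <- random_partial_answers(kb)
    cls <- classify(kb, a)
    if (cls$status != "determined") next
    checked <- checked + 1L
    full <- random_completion(kb, a)
    cls2 <- classify(kb, full)
    expect_identical(cls2$status, "determined")
    expect_equal(cls2$rule_id, cls$rule_id)
    expect_equal(cls2$case_index, cls$case_index)
    expect_identical(cls2$outcome_label, cls$outcome_label)
  }
  expect_gt(checked, 20L)  # the property must actually have been exercised
})

test_that("adding a positive answer never demotes a positive-present group", {
  kb <- kb_fixture()
  set.seed(7)
  for (i in 1:50) {
    a <- random_partial_answers(kb)
    for (g in diag_groups) {
      before <- evaluate_group(kb, a, g)$state
      qs <- kb$questions[kb$questions$group_id == g &
                         kb$questions$kind == "boolean", ]
      unanswered <- setdiff(qs$id, names(a$responses))
      if (length(unanswered) == 0L) next
      q <- qs[qs$id == unanswered[1], ]
      pos_answer <- if (q$positive_when == "negative") "no" else "yes"
      a2 <- answer(a, q$id, pos_answer)
      after <- evaluate_group(kb, a2, g)$state
      if (before == "positive-present") {
        expect_identical(after, "positive-present")
      } else {
        expect_identical(after, "positive-present")  # we added a finding
      }
    }
  }
})

test_that("TENS eligibility partitions all complete contraindication vectors", {
  kb <- kb_fixture()
  g5 <- kb$questions$id[kb$questions$group_id == "G5"]
  combos <- expand.grid(rep(list(c("no", "yes")), length(g5)),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    resp <- stats::setNames(as.character(combos[i, ]), g5)
    a <- answer_set(resp, sex = "female")
    elig <- tens_eligibility(kb, a)
    any_yes <- any(resp == "yes")
    expect_identical(elig,
                     if (any_yes) "cast-prohibited" else "cast-allowed",
                     info = paste(resp, collapse = ","))
  }
})

test_that("TENS eligibility is undetermined on incomplete screens", {
  kb <- kb_fixture()
  a <- answer_set(c(G5.Q1 = "no", G5.Q3 = "no", G5.Q4 = "no",
                    G5.Q5 = "no", G5.Q6 = "no"), sex = "female")
  expect_identical(tens_eligibility(kb, a), "undetermined")
  expect_identical(tens_eligibility(kb, answer_set(c(G5.Q1 = "yes"))),
                   "cast-prohibited")
})

test_that("question sequencing starts at G1.Q1 and skips irrelevant groups", {
  kb <- kb_fixture()
  expect_identical(next_question(kb, answer_set()), "G1.Q1")

  # a positive contraindication screen makes the Ottawa findings (G2)
  # irrelevant: no rule case conjoins a positive-G1 literal with G2
  a <- answer_set(c(G1.Q1 = "yes"), sex = "male")
  nq <- next_question(kb, a)
  expect_identical(nq, "G3-A.Q1")

  # both classification and eligibility determined -> nothing to ask
  full <- canonical_answers(kb, make_assignment())
  expect_null(next_question(kb, full))
})

test_that("classification rejects answers for unknown questions", {
  kb <- kb_fixture()
  a <- answer_set(c("G1.Q99" = "yes"))
  expect_error(classify(kb, a), "G1.Q99")
})
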