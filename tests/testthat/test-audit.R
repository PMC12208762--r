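test_that("brute-force evaluation matches hand-computed rule matches", {
  kb <- kb_fixture()

  hits <- brute_force_classify(kb, make_assignment())
  expect_equal(hits, data.frame(rule_id = 3L, case_index = 1L))

  # hand evaluation: with G1 and G3-B and G4-A positive, G3-A absent, both
  # the fracture case 2 and the sprain case 2 hold simultaneously
  hits <- brute_force_classify(kb, make_assignment(c("G1", "G3-B", "G4-A")))
  expect_equal(hits[order(hits$rule_id), ],
               data.frame(rule_id = c(1L, 2L), case_index = c(2L, 2L)),
               ignore_attr = TRUE)

  hits <- brute_force_classify(kb, make_assignment(c("G2", "G3-A")))
  expect_true(any(hits$rule_id == 1L & hits$case_index == 1L))

  expect_error(brute_force_classify(kb, c(G1 = "positive")), "total")
})

test_that("the packaged rule base is gap-free but overlapping", {
  kb <- kb_fixture()
  rep <- audit_rules(kb)
  expect_equal(rep$n_assignments, 64L)
  expect_length(rep$gap_assignments, 0L)
  expect_gt(length(rep$overlap_assignments), 0L)
  expect_equal(nrow(rep$resolution_table), 64L)
  expect_false(anyNA(rep$resolution_table$rule_id))

  # device-eligibility rules never appear in the diagnostic audit
  all_rules <- unlist(lapply(rep$overlap_assignments,
                             function(o) o$matches$rule_id))
  expect_true(all(c(all_rules, rep$resolution_table$rule_id) %in% 1:3))
})

test_that("a contrived single-case rule base shows 32 gaps", {
  kb <- kb_fixture()
  kb$rules <- kb$rules[c("1", "4", "5")]
  kb$rules[["1"]]$cases <- list(list(case_index = 1L,
                                     condition = any_positive("G1")))
  kb$settings$rule_priority <- 1L
  rep <- audit_rules(kb)
  expect_length(rep$gap_assignments, 32L)
})

test_that("engine and brute-force oracle agree on all 64 assignments", {
  kb <- kb_fixture()
  rep <- audit_rules(kb)
  res <- rep$resolution_table
  for (i in seq_len(nrow(res))) {
    assignment <- stats::setNames(unlist(res[i, diag_groups]), diag_groups)
    cls <- classify(kb, canonical_answers(kb, assignment))
    expect_identical(cls$status, "determined")
    expect_equal(cls$rule_id, res$rule_id[i],
                 info = paste(assignment, collapse = ","))
    expect_equal(cls$case_index, res$case_index[i],
                 info = paste(assignment, collapse = ","))
  }
})

test_that("canonical answer sets realize their assignment deterministically", {
  kb <- kb_fixture()
  set.seed(3)
  for (i in 1:20) {
    assignment <- make_assignment(sample(diag_groups, sample(0:6, 1)))
    a <- canonical_answers(kb, assignment)
    expect_identical(a, canonical_answers(kb, assignment))
    for (g in diag_groups) {
      expect_identical(evaluate_group(kb, a, g)$state,
                       if (assignment[[g]] == "positive") "positive-present"
                       else "absent",
                       info = paste(g, assignment[[g]]))
    }
  }
  # polarity: an absent G2 requires answering yes to the balance question
  a <- canonical_answers(kb, make_assignment())
  expect_identical(unname(a$responses[["G2.Q3"]]), "yes")
  # non-diagnostic G5 is answered all-negative
  g5 <- kb$questions$id[kb$questions$group_id == "G5"]
  expect_true(all(a$responses[g5] == "no"))
  # a positive group is realized by its first question only
  a <- canonical_answers(kb, make_assignment("G3-B"))
  expect_identical(unname(a$responses[["G3-B.Q4"]]), "yes")
  expect_true(all(a$responses[c("G3-B.Q5", "G3-B.Q6", "G3-B.Q7",
                                "G3-B.Q9")] == "no"))
})

test_that("cohort generation is seed-reproducible and leaves the RNG alone", {
  kb <- kb_fixture()
  cfg <- cohort_config(seed = 1, n = 10)
  c1 <- generate_cohort(kb, cfg)
  c2 <- generate_cohort(kb, cfg)
  expect_identical(c1, c2)
  expect_length(c1, 10L)

  set.seed(99)
  before <- stats::runif(5)
  set.seed(99)
  invisible(stats::runif(2))
  state <- .Random.seed
  invisible(generate_cohort(kb, cfg))
  expect_identical(.Random.seed, state)  # caller's stream untouched
  after <- stats::runif(3)
  expect_equal(c(before[1:2], after), before)
})

test_that("degenerate cohort probabilities pin the outcome distribution", {
  kb <- kb_fixture()
  quiet <- generate_cohort(kb, cohort_config(seed = 5, n = 25,
                                             positive_prob = 0,
                                             bmi_elevated_prob = 0))
  outcomes <- vapply(quiet, function(a) classify(kb, a)$outcome_label, "")
  expect_true(all(outcomes == "The patient does not have an injury"))

  cardiac <- generate_cohort(kb, cohort_config(
    seed = 6, n = 25, question_probs = c("G5.Q1" = 1)))
  elig <- vapply(cardiac, function(a) tens_eligibility(kb, a), "")
  expect_true(all(elig == "cast-prohibited"))
})

test_that("generated cohorts always satisfy answer-set invariants", {
  kb <- kb_fixture()
  set.seed(13)
  for (i in 1:5) {
    cfg <- cohort_config(seed = sample.int(1e6, 1), n = 8,
                         positive_prob = stats::runif(1),
                         sex_ratio = stats::runif(1),
                         bmi_elevated_prob = stats::runif(1))
    for (a in generate_cohort(kb, cfg)) {
      expect_s3_class(a, "answer_set")
      expect_true(all(names(a$responses) %in% kb$questions$id))
      expect_true(all(a$responses %in% c("yes", "no")))
      expect_gt(a$weight_kg, 0)
      expect_gt(a$height_cm, 0)
      # pregnancy questions sampled only for female records
      if (a$sex != "female") {
        expect_false(any(c("G1.Q4", "G5.Q2") %in% names(a$responses)))
      }
      # complete: classification and eligibility both resolve
      expect_identical(classify(kb, a)$status, "determined")
      expect_true(tens_eligibility(kb, a) != "undetermined")
    }
  }
  expect_error(cohort_config(seed = 1, n = 5, positive_prob = 1.5), "\\[0, 1\\]")
  expect_error(cohort_config(seed = 1, n = 0), "n must be")
})
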