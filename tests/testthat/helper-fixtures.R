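# Shared fixtures: the packaged KB, the two transcribed case-study patients,
# and generators for random valid knowledge bases and partial answer sets.

kb_fixture <- function() ankle_kb()

case_fracture <- function() {
  read_answers(system.file("extdata", "case_fracture.json",
                           package = "ankletriage"))[[1]]
}

case_sprain <- function() {
  read_answers(system.file("extdata", "case_sprain.json",
                           package = "ankletriage"))[[1]]
}

diag_groups <- c("G1", "G2", "G3-A", "G3-B", "G4-A", "G4-B")

make_assignment <- function(positive = character(0)) {
  stats::setNames(ifelse(diag_groups %in% positive, "positive", "absent"),
                  diag_groups)
}

# A complete all-negative answer set over the packaged KB (every boolean
# question at its non-finding answer, body metrics below the BMI threshold).
all_negative_answers <- function(kb = kb_fixture()) {
  canonical_answers(kb, make_assignment())
}

# Small random—but valid—knowledge base for round-trip property tests.
random_kb <- function(seed) {
  set.seed(seed)
  ng <- sample(2:4, 1)
  gids <- paste0("H", seq_len(ng))
  groups <- lapply(gids, function(g) {
    list(id = g, label = paste("Group", g), role = "fracture-sign")
  })
  questions <- unlist(lapply(gids, function(g) {
    nq <- sample(1:3, 1)
    lapply(seq_len(nq), function(i) {
      list(id = sprintf("%s.Q%d", g, i), group_id = g,
           text = sprintf("Question %d of %s?", i, g),
           kind = "boolean",
           positive_when = sample(c("affirmative", "negative"), 1),
           applicability = "all")
    })
  }), recursive = FALSE)
  random_condition <- function(depth = 0) {
    if (depth >= 2 || stats::runif(1) < 0.5) {
      list(op = sample(c("any", "none"), 1), group = sample(gids, 1))
    } else {
      list(op = sample(c("and", "or"), 1),
           args = lapply(seq_len(sample(2:3, 1)),
                         function(i) random_condition(depth + 1)))
    }
  }
  nr <- sample(1:3, 1)
  rules <- lapply(seq_len(nr), function(r) {
    ncases <- sample(1:2, 1)
    list(rule_id = r, name = sprintf("Rule %d", r), category = "diagnostic",
         outcome_label = sprintf("Outcome %d", r),
         cases = lapply(seq_len(ncases), function(ci) {
           list(case_index = ci, condition = random_condition())
         }))
  })
  load_kb(list(
    version = sprintf("t%d", seed),
    groups = groups,
    questions = questions,
    rules = rules,
    recovery_plans = list(list(injury_key = "generic",
                               healing_duration_weeks = 4L,
                               residual_symptom_horizon_months = 2L,
                               provisional = TRUE,
                               phases = list(list(weeks = "1-4",
                                                  instruction = "Rest.")))),
    settings = list(bmi_elevated_threshold = 25,
                    rule_priority = as.list(seq_len(nr)),
                    outcome_paths = list(),
                    compatibility_flags = list())))
}

# Random partial answer set: complete canonical answers for a random
# assignment, with a random subset of responses removed.
random_partial_answers <- function(kb, keep_frac = 0.6) {
  assignment <- make_assignment(sample(diag_groups,
                                       sample(0:length(diag_groups), 1)))
  full <- canonical_answers(kb, assignment)
  keep <- stats::runif(length(full$responses)) < keep_frac
  a <- answer_set(full$responses[keep], sex = full$sex,
                  weight_kg = if (stats::runif(1) < 0.5) full$weight_kg else NA,
                  height_cm = if (stats::runif(1) < 0.5) full$height_cm else NA)
  a
}

# Complete a partial answer set with arbitrary answers to every remaining
# applicable question.
random_completion <- function(kb, answers) {
  resp <- answers$responses
  for (i in seq_len(nrow(kb$questions))) {
    q <- kb$questions[i, , drop = FALSE]
    if (q$kind != "boolean") next
    if (q$applicability == "female-only" && answers$sex != "female") next
    if (!q$id %in% names(resp)) {
      resp[[q$id]] <- sample(c("yes", "no"), 1)
    }
  }
  w <- if (is.na(answers$weight_kg)) stats::runif(1, 50, 110) else answers$weight_kg
  h <- if (is.na(answers$height_cm)) stats::runif(1, 150, 195) else answers$height_cm
  answer_set(resp, sex = answers$sex, weight_kg = w, height_cm = h)
}
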