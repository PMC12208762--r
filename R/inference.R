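#' Body mass index
#'
#' @param weight_kg body mass in kilograms (> 0)
#' @param height_cm height in centimeters (> 0)
#' @return BMI in kg/m^2
#' @examples
#' compute_bmi(70, 175)
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (!is.finite(weight_kg) || weight_kg <= 0) {
    stop("weight_kg must be a positive number", call. = FALSE)
  }
  if (!is.finite(height_cm) || height_cm <= 0) {
    stop("height_cm must be a positive number", call. = FALSE)
  }
  weight_kg / (height_cm / 100)^2
}

#' Is a BMI elevated?
#'
#' The comparison is inclusive: a BMI exactly at the threshold counts as
#' elevated. The threshold defaults to the knowledge base's setting
#' (25 kg/m^2, the WHO overweight cut-off).
#'
#' @param bmi BMI in kg/m^2
#' @param threshold cut-off in kg/m^2
#' @return logical
#' @export
bmi_elevated <- function(bmi, threshold = 25) {
  stopifnot(is.finite(bmi), is.finite(threshold))
  bmi >= threshold
}

# Facts derived from body metrics; bmi is NA unless both metrics are present.
derived_facts <- function(kb, answers) {
  if (!is.na(answers$weight_kg) && !is.na(answers$height_cm)) {
    bmi <- compute_bmi(answers$weight_kg, answers$height_cm)
    list(bmi = bmi,
         bmi_elevated = bmi_elevated(bmi, kb$settings$bmi_elevated_threshold))
  } else {
    list(bmi = NA_real_, bmi_elevated = NA)
  }
}

# Tri-state finding for one question: TRUE = positive clinical finding,
# FALSE = finding ruled out, NA = undetermined. Polarity-aware: for the
# weight-bearing/balance question the positive finding is the "no" answer.
question_finding <- function(kb, answers, qrow, facts) {
  if (qrow$kind == "body-metric") {
    return(facts$bmi_elevated)
  }
  applicable <- qrow$applicability == "all" || answers$sex == "female"
  resp <- get_response(answers, qrow$id)
  if (is.na(resp)) {
    if (!applicable) return(FALSE)  # auto-resolved, e.g. pregnancy for males
    return(NA)
  }
  affirmative <- identical(resp, "yes")
  if (qrow$positive_when == "negative") !affirmative else affirmative
}

#' Evaluate the aggregate finding of one question group
#'
#' Aggregation is tri-state. A single positive finding makes the group
#' \code{positive-present} immediately, regardless of unanswered questions
#' (the "yes in any" aggregate short-circuits). The group is \code{absent}
#' only when every applicable question is answered and none is positive;
#' otherwise it is \code{undetermined}. Female-only questions are
#' auto-resolved to "no finding" for non-female patients, and body-metric
#' questions contribute their thresholded BMI value.
#'
#' When the compatibility flag \code{exclude_G1_Q6_from_aggregate} is on,
#' question G1.Q6 (the neurological red-flag screen) is left out of the G1
#' aggregate; a positive answer to it is then reported separately as a red
#' flag rather than as an Ottawa-rule contraindication.
#'
#' @param kb a \code{knowledge_base}
#' @param answers an \code{answer_set}
#' @param group_id group to evaluate
#' @return object of class \code{group_finding}: state
#'   (\code{positive-present} / \code{absent} / \code{undetermined}),
#'   the contributing positive question ids and the unanswered ones
#' @export
evaluate_group <- function(kb, answers, group_id) {
  if (!group_id %in% kb$groups$id) {
    stop(sprintf("unknown group '%s'", group_id), call. = FALSE)
  }
  check_answers(kb, answers)
  facts <- derived_facts(kb, answers)
  qs <- kb$questions[kb$questions$group_id == group_id, , drop = FALSE]
  if (isTRUE(kb$settings$compatibility_flags$exclude_G1_Q6_from_aggregate)) {
    qs <- qs[qs$id != "G1.Q6", , drop = FALSE]
  }
  vals <- vapply(seq_len(nrow(qs)), function(i) {
    question_finding(kb, answers, qs[i, , drop = FALSE], facts)
  }, NA)
  names(vals) <- qs$id
  state <- if (any(vals, na.rm = TRUE)) {
    "positive-present"
  } else if (!anyNA(vals)) {
    "absent"
  } else {
    "undetermined"
  }
  structure(list(group_id = group_id,
                 state = state,
                 positive_questions = names(vals)[which(vals)],
                 unanswered_questions = names(vals)[is.na(vals)],
                 values = vals),
            class = "group_finding")
}

#' @export
print.group_finding <- function(x, ...) {
  cat(sprintf("<group_finding %s: %s>\n", x$group_id, x$state))
  invisible(x)
}

# positive-present -> TRUE, absent -> FALSE, undetermined -> NA
finding_tristate <- function(finding) {
  if (inherits(finding, "group_finding")) finding <- finding$state
  switch(finding,
         "positive-present" = TRUE,
         "positive" = TRUE,
         "absent" = FALSE,
         "undetermined" = NA,
         stop(sprintf("unknown finding state '%s'", finding), call. = FALSE))
}

#' Evaluate a rule condition under strong Kleene three-valued logic
#'
#' Leaves map group findings to truth values (\code{any_positive}:
#' positive-present is true, absent is false, undetermined is unknown;
#' \code{none_positive} is its negation) and AND/OR combine them by the
#' strong Kleene tables, which R's native three-valued \code{&}/\code{|}
#' over \code{TRUE}/\code{FALSE}/\code{NA} implement exactly. The result is
#' therefore sound with respect to every completion of the unanswered
#' questions: a definite TRUE or FALSE can never be overturned by more
#' answers.
#'
#' @param expr a condition (see [any_positive()])
#' @param findings named list of \code{group_finding} objects, or a named
#'   logical/character vector of group states, covering every group the
#'   expression references
#' @return list with \code{value} (TRUE/FALSE/NA) and \code{leaves}, a data
#'   frame of every leaf with its tri-state value
#' @export
evaluate_condition <- function(expr, findings) {
  tri <- findings_to_tristate(findings)
  missing <- setdiff(condition_groups(expr), names(tri))
  if (length(missing)) {
    stop(sprintf("no finding supplied for group(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  leaves <- list()
  eval_node <- function(cond) {
    switch(cond$op,
      any = {
        v <- tri[[cond$group]]
        leaves[[length(leaves) + 1L]] <<- data.frame(
          leaf = sprintf("any(%s)", cond$group), op = "any",
          group = cond$group, value = tristate_chr(v), stringsAsFactors = FALSE)
        v
      },
      none = {
        v <- !tri[[cond$group]]
        leaves[[length(leaves) + 1L]] <<- data.frame(
          leaf = sprintf("none(%s)", cond$group), op = "none",
          group = cond$group, value = tristate_chr(v), stringsAsFactors = FALSE)
        v
      },
      and = Reduce(`&`, lapply(cond$args, eval_node)),
      or = Reduce(`|`, lapply(cond$args, eval_node))
    )
  }
  value <- eval_node(expr)
  list(value = value, leaves = do.call(rbind, leaves))
}

findings_to_tristate <- function(findings) {
  if (is.logical(findings)) return(as.list(findings))
  if (is.character(findings)) {
    return(stats::setNames(lapply(findings, finding_tristate), names(findings)))
  }
  stats::setNames(lapply(findings, finding_tristate), names(findings))
}

tristate_chr <- function(v) {
  if (is.na(v)) "unknown" else if (v) "true" else "false"
}

#' Classify a patient by forward chaining over the diagnostic rules
#'
#' Starting from the question-level facts, group aggregates are derived and
#' the diagnostic rules are evaluated in priority order (by default rule 1,
#' fracture, before rule 2, sprain, before rule 3, no injury -- a possible
#' fracture is never under-triaged), cases in their published order. The
#' first case that evaluates definitely true fires, provided every
#' higher-priority case is definitely false: a \code{determined}
#' classification is therefore invariant under all completions of the
#' unanswered questions and is never retracted by further answers. If any
#' higher-priority case is still unknown, the status is
#' \code{needs-more-answers} and the blocking leaves are reported.
#'
#' @param kb a \code{knowledge_base}
#' @param answers an \code{answer_set}
#' @param mode \code{NULL} to use the knowledge base's own compatibility
#'   flags, or \code{"strict"} / \code{"compatibility"} to force the
#'   corresponding semantics (the compatibility mode excludes G1.Q6 from
#'   the G1 aggregate; see [evaluate_group()])
#' @return object of class \code{classification} with \code{status}
#'   ("determined" or "needs-more-answers"), \code{rule_id},
#'   \code{case_index}, \code{outcome_label}, a leaf-level evaluation
#'   \code{trace}, the \code{blocking} leaves when undetermined, the group
#'   \code{findings}, the \code{mode} used and any \code{red_flags}
#' @examples
#' kb <- ankle_kb()
#' pt <- read_answers(system.file("extdata", "case_fracture.json",
#'                                package = "ankletriage"))[[1]]
#' classify(kb, pt)
#' @export
classify <- function(kb, answers, mode = NULL) {
  kb <- apply_mode(kb, mode)
  check_answers(kb, answers)
  issues <- validate_kb(kb)
  if (any(issues$severity == "error")) {
    stop("invalid knowledge base; see validate_kb()", call. = FALSE)
  }

  groups <- diagnostic_groups(kb)
  findings <- stats::setNames(
    lapply(groups, function(g) evaluate_group(kb, answers, g)), groups)

  trace <- list()
  pending <- list()   # leaves of still-unknown cases ahead of any firing case
  fired <- NULL
  for (r in diagnostic_rules(kb)) {
    for (cs in r$cases) {
      ev <- evaluate_condition(cs$condition, findings)
      lv <- ev$leaves
      lv$rule_id <- r$rule_id
      lv$case_index <- cs$case_index
      lv$case_value <- tristate_chr(ev$value)
      trace[[length(trace) + 1L]] <- lv
      if (isTRUE(ev$value)) {
        fired <- list(rule = r, case = cs)
        break
      }
      if (is.na(ev$value)) {
        pending[[length(pending) + 1L]] <-
          lv[lv$value == "unknown", , drop = FALSE]
      }
    }
    if (!is.null(fired)) break
  }
  trace <- do.call(rbind, trace)[, c("rule_id", "case_index", "leaf",
                                     "value", "case_value")]

  red_flags <- character(0)
  if (isTRUE(kb$settings$compatibility_flags$exclude_G1_Q6_from_aggregate) &&
      identical(get_response(answers, "G1.Q6"), "yes")) {
    red_flags <- paste("G1.Q6 answered yes: neurological red-flag conditions",
                       "reported; excluded from the G1 aggregate by the",
                       "compatibility flag")
  }

  base <- list(mode = kb_mode(kb), kb_version = kb$version,
               findings = findings, trace = trace, red_flags = red_flags)

  if (!is.null(fired) && length(pending) == 0L) {
    cls <- c(list(status = "determined",
                  rule_id = fired$rule$rule_id,
                  case_index = fired$case$case_index,
                  outcome_label = fired$rule$outcome_label,
                  blocking = NULL), base)
  } else if (length(pending) > 0L || is.null(fired)) {
    blocking <- if (length(pending)) unique(do.call(rbind, pending)) else NULL
    if (is.null(blocking) && is.null(fired)) {
      stop("no diagnostic rule matched a complete answer set; the rule base has gaps",
           call. = FALSE)
    }
    cls <- c(list(status = "needs-more-answers",
                  rule_id = NA_integer_, case_index = NA_integer_,
                  outcome_label = NA_character_,
                  blocking = blocking), base)
  }
  structure(cls, class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification> mode=%s kb=v%s\n", x$mode, x$kb_version))
  if (x$status == "determined") {
    cat(sprintf("  Rule %d: Case %d -> %s\n",
                x$rule_id, x$case_index, x$outcome_label))
  } else {
    cat("  needs more answers; blocking groups:",
        paste(unique(x$blocking$group), collapse = ", "), "\n")
  }
  for (rf in x$red_flags) cat("  red flag:", rf, "\n")
  invisible(x)
}

#' Screen TENS / cast eligibility
#'
#' The contraindication screen (group G5: heart disease, pregnancy,
#' seizures, convulsions, lymphedema, blood clots, epilepsy) is prohibitive:
#' any positive answer prohibits cast and TENS use, and eligibility is
#' granted only when every applicable G5 question is answered negative.
#'
#' @param kb a \code{knowledge_base}
#' @param answers an \code{answer_set}
#' @return \code{"cast-allowed"}, \code{"cast-prohibited"} or
#'   \code{"undetermined"}
#' @export
tens_eligibility <- function(kb, answers) {
  f <- evaluate_group(kb, answers, "G5")
  switch(f$state,
         "positive-present" = "cast-prohibited",
         "absent" = "cast-allowed",
         "undetermined")
}

#' Next question to ask
#'
#' Questionnaire sequencing for interactive triage: questions are asked in
#' the knowledge base's group order (G1, G2, G3-A, G3-B, G4-A, G4-B, G5),
#' each group in its published question order, but whole groups are skipped
#' once they can no longer affect the still-undetermined part of the
#' classification or the eligibility screen. A group remains relevant to the
#' classification only while some rule case that could still fire has an
#' unknown leaf over it; G5 remains relevant while eligibility is
#' undetermined.
#'
#' @inheritParams classify
#' @return the next question id, or \code{NULL} when both classification and
#'   eligibility are already determined
#' @export
next_question <- function(kb, answers, mode = NULL) {
  kb <- apply_mode(kb, mode)
  cls <- classify(kb, answers)
  elig <- tens_eligibility(kb, answers)

  relevant <- character(0)
  if (cls$status != "determined") relevant <- unique(cls$blocking$group)
  if (elig == "undetermined") relevant <- c(relevant, "G5")
  if (length(relevant) == 0L) return(NULL)

  facts <- derived_facts(kb, answers)
  for (g in kb$groups$id) {
    if (!g %in% relevant) next
    qs <- kb$questions[kb$questions$group_id == g, , drop = FALSE]
    for (i in seq_len(nrow(qs))) {
      q <- qs[i, , drop = FALSE]
      if (q$applicability == "female-only" && answers$sex != "female") next
      unanswered <- if (q$kind == "body-metric") {
        is.na(facts$bmi)
      } else {
        is.na(get_response(answers, q$id))
      }
      if (unanswered) return(q$id)
    }
  }
  NULL
}

#' Record an answer on an answer set
#'
#' Convenience for interactive flows: returns a new answer set with one
#' question answered (or, for the body-metric question, the weight and
#' height filled in).
#'
#' @param answers an \code{answer_set}
#' @param question_id question being answered
#' @param value \code{"yes"} or \code{"no"} for boolean questions
#' @param weight_kg,height_cm metrics for body-metric questions
#' @return updated \code{answer_set}
#' @export
answer <- function(answers, question_id, value = NULL,
                   weight_kg = NULL, height_cm = NULL) {
  stopifnot(inherits(answers, "answer_set"))
  if (!is.null(weight_kg)) answers$weight_kg <- as.numeric(weight_kg)
  if (!is.null(height_cm)) answers$height_cm <- as.numeric(height_cm)
  if (!is.null(value)) {
    value <- match.arg(value, c("yes", "no"))
    answers$responses[[question_id]] <- value
  }
  answer_set(answers$responses, answers$sex, answers$weight_kg, answers$height_cm)
}
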