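#' Brute-force evaluation of the diagnostic rule table
#'
#' Independent oracle for the inference engine: given a total assignment of
#' \code{positive}/\code{absent} to the six diagnostic groups, evaluates
#' every diagnostic case condition literally, with plain two-valued
#' recursion over the condition tree -- no group aggregation, no three-valued
#' logic, no priority. Returns every (rule, case) whose condition holds.
#'
#' @param kb a \code{knowledge_base}
#' @param assignment named character vector mapping each diagnostic group id
#'   to \code{"positive"} or \code{"absent"} (a named logical vector with
#'   TRUE = positive is also accepted)
#' @return data frame with columns \code{rule_id}, \code{case_index}; zero
#'   rows when no case matches
#' @examples
#' kb <- ankle_kb()
#' all_absent <- setNames(rep("absent", 6),
#'                        c("G1", "G2", "G3-A", "G3-B", "G4-A", "G4-B"))
#' brute_force_classify(kb, all_absent)
#' @export
brute_force_classify <- function(kb, assignment) {
  pos <- assignment_positive(kb, assignment)
  eval2 <- function(cond) {
    switch(cond$op,
      any = pos[[cond$group]],
      none = !pos[[cond$group]],
      and = all(vapply(cond$args, eval2, NA)),
      or = any(vapply(cond$args, eval2, NA)))
  }
  hits <- list()
  for (r in Filter(function(r) r$category == "diagnostic", kb$rules)) {
    for (cs in r$cases) {
      if (eval2(cs$condition)) {
        hits[[length(hits) + 1L]] <- data.frame(rule_id = r$rule_id,
                                                case_index = cs$case_index)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(rule_id = integer(0), case_index = integer(0))
}

assignment_positive <- function(kb, assignment) {
  groups <- diagnostic_groups(kb)
  if (is.logical(assignment)) {
    pos <- assignment
  } else {
    stopifnot(all(assignment %in% c("positive", "absent")))
    pos <- assignment == "positive"
    names(pos) <- names(assignment)
  }
  missing <- setdiff(groups, names(pos))
  if (length(missing)) {
    stop(sprintf("assignment must be total over the diagnostic groups; missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  as.list(pos)
}

# All 2^k positive/absent assignments over the diagnostic groups, in a
# fixed enumeration order.
all_assignments <- function(kb) {
  groups <- diagnostic_groups(kb)
  grid <- expand.grid(rep(list(c("absent", "positive")), length(groups)),
                      stringsAsFactors = FALSE)
  names(grid) <- groups
  lapply(seq_len(nrow(grid)), function(i) {
    stats::setNames(as.character(grid[i, ]), groups)
  })
}

# First (rule, case) under the KB's priority order among brute-force hits.
priority_resolve <- function(kb, hits) {
  if (nrow(hits) == 0L) return(NULL)
  prio <- match(hits$rule_id, kb$settings$rule_priority)
  ord <- order(prio, hits$case_index)
  hits[ord[1], , drop = FALSE]
}

#' Audit the diagnostic rule base for gaps and overlaps
#'
#' Exhaustively enumerates every assignment of positive/absent to the
#' diagnostic groups (64 for the packaged base) and evaluates each case
#' condition by brute force. An assignment firing no diagnostic rule is a
#' gap (the rule base would be silent on a fully examined patient); one
#' firing several is an overlap, resolved in practice by the documented
#' severity priority (fracture before sprain before no-injury). The audit
#' works at group-aggregate level because every rule condition factors
#' through the group aggregates.
#'
#' @param kb a \code{knowledge_base}
#' @return object of class \code{audit_report}: \code{gap_assignments}
#'   (list of assignments firing nothing), \code{overlap_assignments}
#'   (list of \code{list(assignment, matches)}), and a
#'   \code{resolution_table} giving the priority-resolved (rule, case) per
#'   assignment
#' @export
audit_rules <- function(kb) {
  issues <- validate_kb(kb)
  if (any(issues$severity == "error")) {
    stop("invalid knowledge base; see validate_kb()", call. = FALSE)
  }
  assignments <- all_assignments(kb)
  gaps <- list()
  overlaps <- list()
  rows <- list()
  for (a in assignments) {
    hits <- brute_force_classify(kb, a)
    if (nrow(hits) == 0L) {
      gaps[[length(gaps) + 1L]] <- a
      res <- data.frame(rule_id = NA_integer_, case_index = NA_integer_)
    } else {
      if (nrow(hits) > 1L) {
        overlaps[[length(overlaps) + 1L]] <- list(assignment = a, matches = hits)
      }
      res <- priority_resolve(kb, hits)
    }
    rows[[length(rows) + 1L]] <- cbind(
      as.data.frame(as.list(a), check.names = FALSE, stringsAsFactors = FALSE),
      res)
  }
  structure(list(n_assignments = length(assignments),
                 gap_assignments = gaps,
                 overlap_assignments = overlaps,
                 resolution_table = do.call(rbind, rows)),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<audit_report> %d assignments enumerated\n", x$n_assignments))
  cat(sprintf("  gaps: %d\n", length(x$gap_assignments)))
  cat(sprintf("  overlaps: %d\n", length(x$overlap_assignments)))
  invisible(x)
}

#' Canonical complete answer set realizing a finding assignment
#'
#' Deterministically builds a fully answered questionnaire whose group
#' aggregates reproduce a given positive/absent assignment. Polarity is
#' respected (an absent G2 requires answering "yes" to the
#' balance/weight-bearing question), a positive group is realized by its
#' first boolean question alone, groups outside the assignment (G5) are
#' answered all-negative, and the body metrics are fixed below the BMI
#' threshold so the thresholded questions never contribute a finding.
#'
#' @inheritParams brute_force_classify
#' @return a complete \code{answer_set}
#' @export
canonical_answers <- function(kb, assignment) {
  pos <- assignment_positive(kb, assignment)
  responses <- character(0)
  for (g in kb$groups$id) {
    qs <- kb$questions[kb$questions$group_id == g &
                       kb$questions$kind == "boolean", , drop = FALSE]
    want_positive <- isTRUE(pos[[g]])
    for (i in seq_len(nrow(qs))) {
      make_finding <- want_positive && i == 1L
      affirmative <- xor(make_finding, qs$positive_when[i] == "negative")
      responses[[qs$id[i]]] <- if (affirmative) "yes" else "no"
    }
  }
  # 70 kg / 175 cm -> BMI 22.9, below the packaged 25 kg/m^2 threshold
  answer_set(responses, sex = "female", weight_kg = 70, height_cm = 175)
}

#' Synthetic-cohort configuration
#'
#' @param seed integer RNG seed; the generator draws from an isolated
#'   stream, leaving the caller's RNG state untouched
#' @param n cohort size (>= 1)
#' @param sex_ratio probability a patient is female
#' @param positive_prob default probability that a boolean question shows
#'   its positive clinical finding
#' @param question_probs optional named vector of per-question overrides
#' @param bmi_elevated_prob probability the sampled BMI is at or above the
#'   knowledge base's threshold (one body, one BMI: the same sampled
#'   weight/height feeds every body-metric question)
#' @param height_mean,height_sd normal parameters for height in cm
#' @return a \code{cohort_config}
#' @export
cohort_config <- function(seed, n, sex_ratio = 0.5, positive_prob = 0.15,
                          question_probs = NULL, bmi_elevated_prob = 0.15,
                          height_mean = 170, height_sd = 10) {
  probs <- c(sex_ratio = sex_ratio, positive_prob = positive_prob,
             bmi_elevated_prob = bmi_elevated_prob, unlist(question_probs))
  if (any(!is.finite(probs) | probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(n) || n < 1) stop("cohort size n must be >= 1", call. = FALSE)
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 sex_ratio = sex_ratio, positive_prob = positive_prob,
                 question_probs = unlist(question_probs),
                 bmi_elevated_prob = bmi_elevated_prob,
                 height_mean = height_mean, height_sd = height_sd),
            class = "cohort_config")
}

# Run code under a dedicated seed, restoring the caller's RNG state.
with_isolated_rng <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded synthetic patient cohort
#'
#' Draws \code{n} independent complete answer sets under the configured
#' per-question positive-finding probabilities. Answers are sampled at the
#' finding level and translated through each question's polarity, so a
#' positive-finding draw on the balance question yields the answer "no".
#' The pregnancy questions are sampled only for female patients. Identical
#' \code{(seed, config)} reproduce an identical cohort.
#'
#' @param kb a \code{knowledge_base}
#' @param config a [cohort_config()]
#' @return list of \code{answer_set}
#' @export
generate_cohort <- function(kb, config) {
  stopifnot(inherits(config, "cohort_config"))
  threshold <- kb$settings$bmi_elevated_threshold
  qprob <- function(qid) {
    if (!is.null(config$question_probs) && qid %in% names(config$question_probs))
      config$question_probs[[qid]] else config$positive_prob
  }
  with_isolated_rng(config$seed, {
    lapply(seq_len(config$n), function(i) {
      sex <- if (stats::runif(1) < config$sex_ratio) "female" else "male"
      responses <- character(0)
      for (j in seq_len(nrow(kb$questions))) {
        q <- kb$questions[j, , drop = FALSE]
        if (q$kind != "boolean") next
        if (q$applicability == "female-only" && sex != "female") next
        finding <- stats::runif(1) < qprob(q$id)
        affirmative <- xor(finding, q$positive_when == "negative")
        responses[[q$id]] <- if (affirmative) "yes" else "no"
      }
      height <- max(stats::rnorm(1, config$height_mean, config$height_sd), 120)
      elevated <- stats::runif(1) < config$bmi_elevated_prob
      offset <- abs(stats::rnorm(1, 3, 2))
      bmi <- if (elevated) threshold + offset else max(threshold - offset, 15)
      weight <- bmi * (height / 100)^2
      answer_set(responses, sex = sex, weight_kg = weight, height_cm = height)
    })
  })
}
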