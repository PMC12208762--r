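#' Load a declarative knowledge-base document
#'
#' Reads a knowledge base from JSON (canonical) or YAML (accepted) and
#' materializes it into a \code{knowledge_base} object. The document schema
#' is published at \code{system.file("extdata", "kb.schema.json",
#' package = "ankletriage")}; structural violations raise an error naming
#' the offending field, including dangling group references from questions
#' or rule conditions.
#'
#' @param source path to a \code{.json}/\code{.yaml}/\code{.yml} file, a
#'   single JSON string, or an already-parsed list with the document's
#'   top-level keys.
#' @return an object of class \code{knowledge_base}
#' @seealso [validate_kb()], [serialize_kb()], [ankle_kb()]
#' @export
load_kb <- function(source) {
  x <- if (is.list(source)) {
    source
  } else if (is.character(source) && length(source) == 1L) {
    if (file.exists(source)) {
      ext <- tolower(tools::file_ext(source))
      if (ext %in% c("yaml", "yml")) {
        yaml::read_yaml(source)
      } else {
        jsonlite::fromJSON(source, simplifyVector = FALSE)
      }
    } else if (grepl("^\\s*\\{", source)) {
      jsonlite::fromJSON(source, simplifyVector = FALSE)
    } else {
      stop(sprintf("knowledge-base file not found: '%s'", source), call. = FALSE)
    }
  } else {
    stop("'source' must be a file path, a JSON string, or a list", call. = FALSE)
  }
  kb_from_list(x)
}

# Materialize a parsed document into a typed knowledge_base, failing fast on
# schema violations with a message naming the path and field.
kb_from_list <- function(x) {
  req <- function(obj, field, where) {
    if (is.null(obj[[field]])) {
      stop(sprintf("knowledge base: missing field '%s' at %s", field, where),
           call. = FALSE)
    }
    obj[[field]]
  }
  for (top in c("version", "groups", "questions", "rules",
                "recovery_plans", "settings")) {
    req(x, top, "top level")
  }

  groups <- do.call(rbind, lapply(seq_along(x$groups), function(i) {
    g <- x$groups[[i]]
    where <- sprintf("groups[%d]", i)
    data.frame(id = as.character(req(g, "id", where)),
               label = as.character(req(g, "label", where)),
               role = as.character(req(g, "role", where)),
               stringsAsFactors = FALSE)
  }))

  questions <- do.call(rbind, lapply(seq_along(x$questions), function(i) {
    q <- x$questions[[i]]
    where <- sprintf("questions[%d]", i)
    data.frame(id = as.character(req(q, "id", where)),
               group_id = as.character(req(q, "group_id", where)),
               text = as.character(req(q, "text", where)),
               kind = as.character(req(q, "kind", where)),
               positive_when = as.character(req(q, "positive_when", where)),
               applicability = as.character(req(q, "applicability", where)),
               stringsAsFactors = FALSE)
  }))

  bad_q <- setdiff(unique(questions$group_id), groups$id)
  if (length(bad_q)) {
    stop(sprintf("knowledge base: questions reference undefined group(s): %s",
                 paste(bad_q, collapse = ", ")), call. = FALSE)
  }

  rules <- lapply(seq_along(x$rules), function(i) {
    r <- x$rules[[i]]
    where <- sprintf("rules[%d]", i)
    cases <- lapply(seq_along(req(r, "cases", where)), function(j) {
      cs <- r$cases[[j]]
      cwhere <- sprintf("%s.cases[%d]", where, j)
      cond <- condition_from_list(req(cs, "condition", cwhere))
      probs <- check_condition(cond, groups$id, sprintf("%s.condition", cwhere))
      if (length(probs)) stop(paste(probs, collapse = "; "), call. = FALSE)
      list(case_index = as.integer(req(cs, "case_index", cwhere)),
           condition = cond)
    })
    list(rule_id = as.integer(req(r, "rule_id", where)),
         name = as.character(r$name %||% ""),
         category = as.character(req(r, "category", where)),
         outcome_label = as.character(req(r, "outcome_label", where)),
         cases = cases)
  })
  names(rules) <- vapply(rules, function(r) as.character(r$rule_id), "")

  plans <- lapply(seq_along(x$recovery_plans), function(i) {
    p <- x$recovery_plans[[i]]
    where <- sprintf("recovery_plans[%d]", i)
    phases <- lapply(p$phases %||% list(), function(ph) {
      list(weeks = as.character(ph$weeks), instruction = as.character(ph$instruction))
    })
    structure(
      list(injury_key = as.character(req(p, "injury_key", where)),
           label = as.character(p$label %||% p$injury_key),
           healing_duration_weeks = as.integer(req(p, "healing_duration_weeks", where)),
           residual_symptom_horizon_months =
             as.integer(req(p, "residual_symptom_horizon_months", where)),
           provisional = isTRUE(p$provisional),
           phases = phases),
      class = "recovery_plan")
  })
  names(plans) <- vapply(plans, `[[`, "", "injury_key")

  s <- x$settings
  settings <- list(
    bmi_elevated_threshold = as.numeric(s$bmi_elevated_threshold %||% 25),
    rule_priority = as.integer(unlist(s$rule_priority %||% list())),
    outcome_paths = lapply(s$outcome_paths %||% list(), as.character),
    compatibility_flags = lapply(s$compatibility_flags %||% list(), isTRUE)
  )

  structure(
    list(version = as.character(x$version),
         groups = groups,
         questions = questions,
         rules = rules,
         recovery_plans = plans,
         settings = settings),
    class = "knowledge_base")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged ankle-triage knowledge base
#'
#' Returns the knowledge base shipped with the package: 7 question groups,
#' 32 questions, 5 production rules (3 diagnostic, 2 device-eligibility)
#' with 10 condition cases in total, and recovery plans for Weber A and
#' Weber B fractures and for sprains. Question texts and outcome labels are
#' stored verbatim as published.
#'
#' @return a \code{knowledge_base}
#' @examples
#' kb <- ankle_kb()
#' length(kb$rules)
#' @export
ankle_kb <- function() {
  load_kb(system.file("extdata", "ankle_kb.json", package = "ankletriage",
                      mustWork = TRUE))
}

#' Validate a knowledge base
#'
#' Checks every structural invariant of the knowledge base and returns the
#' findings as data, not exceptions: an empty data frame means the base is
#' valid. Checked invariants include unique group and question ids,
#' non-empty groups, body-metric questions using the threshold polarity,
#' consecutive case indices starting at 1, a rule priority covering exactly
#' the diagnostic rules, a positive BMI threshold, and recovery-plan
#' timelines whose residual-symptom horizon is at least the healing
#' duration.
#'
#' @param kb a \code{knowledge_base}
#' @return data frame with columns \code{severity} ("error" or "warning"),
#'   \code{location}, \code{message}; zero rows when the base is valid
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  issues <- list()
  add <- function(severity, location, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, location = location, message = message,
      stringsAsFactors = FALSE)
  }

  if (anyDuplicated(kb$groups$id)) {
    add("error", "groups", sprintf("duplicate group id(s): %s",
        paste(unique(kb$groups$id[duplicated(kb$groups$id)]), collapse = ", ")))
  }
  if (anyDuplicated(kb$questions$id)) {
    add("error", "questions", sprintf("duplicate question id(s): %s",
        paste(unique(kb$questions$id[duplicated(kb$questions$id)]), collapse = ", ")))
  }
  empty <- setdiff(kb$groups$id, kb$questions$group_id)
  for (g in empty) add("error", sprintf("groups.%s", g), "group has no questions")
  bad <- setdiff(unique(kb$questions$group_id), kb$groups$id)
  for (g in bad) add("error", "questions", sprintf("undefined group '%s'", g))

  bm <- kb$questions[kb$questions$kind == "body-metric", ]
  for (i in seq_len(nrow(bm))) {
    if (bm$positive_when[i] != "threshold-exceeded") {
      add("error", sprintf("questions.%s", bm$id[i]),
          "body-metric question must have positive_when = 'threshold-exceeded'")
    }
  }
  bl <- kb$questions[kb$questions$kind == "boolean" &
                     !kb$questions$positive_when %in% c("affirmative", "negative"), ]
  for (i in seq_len(nrow(bl))) {
    add("error", sprintf("questions.%s", bl$id[i]),
        "boolean question must be positive on 'affirmative' or 'negative'")
  }

  seen_rule <- integer(0)
  for (r in kb$rules) {
    loc <- sprintf("rules.%d", r$rule_id)
    if (r$rule_id %in% seen_rule) add("error", loc, "duplicate rule id")
    seen_rule <- c(seen_rule, r$rule_id)
    if (!r$category %in% c("diagnostic", "device-eligibility")) {
      add("error", loc, sprintf("unknown category '%s'", r$category))
    }
    if (!nzchar(r$outcome_label)) add("error", loc, "empty outcome label")
    idx <- vapply(r$cases, `[[`, 0L, "case_index")
    if (!identical(idx, seq_along(idx))) {
      add("error", loc, "case indices must be consecutive starting at 1")
    }
    for (cs in r$cases) {
      probs <- check_condition(cs$condition, kb$groups$id,
                               sprintf("%s.case%d", loc, cs$case_index))
      for (p in probs) add("error", loc, p)
    }
  }

  diag_ids <- vapply(Filter(function(r) r$category == "diagnostic", kb$rules),
                     `[[`, 0L, "rule_id")
  if (!setequal(kb$settings$rule_priority, diag_ids) ||
      anyDuplicated(kb$settings$rule_priority)) {
    add("error", "settings.rule_priority",
        "rule_priority must be a permutation of the diagnostic rule ids")
  }
  if (!is.finite(kb$settings$bmi_elevated_threshold) ||
      kb$settings$bmi_elevated_threshold <= 0) {
    add("error", "settings.bmi_elevated_threshold", "threshold must be positive")
  }

  for (p in kb$recovery_plans) {
    loc <- sprintf("recovery_plans.%s", p$injury_key)
    if (p$healing_duration_weeks <= 0) {
      add("error", loc, "healing duration must be positive")
    }
    # horizon comparable in weeks: 1 month ~ 52/12 weeks
    if (p$residual_symptom_horizon_months * 52 / 12 < p$healing_duration_weeks) {
      add("error", loc, "residual-symptom horizon shorter than healing duration")
    }
  }

  if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(0), location = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

#' Serialize a knowledge base to its declarative document form
#'
#' Inverse of [load_kb()]: \code{load_kb(serialize_kb(kb))} reproduces
#' \code{kb} exactly. Refuses to serialize a base that fails
#' [validate_kb()].
#'
#' @param kb a \code{knowledge_base}
#' @param path optional output file; format inferred from the extension
#'   (\code{.yaml}/\code{.yml} for YAML, JSON otherwise) unless given
#' @param format "json" or "yaml"
#' @return the document text, invisibly when written to \code{path}
#' @export
serialize_kb <- function(kb, path = NULL, format = NULL) {
  issues <- validate_kb(kb)
  if (any(issues$severity == "error")) {
    stop("refusing to serialize an invalid knowledge base; see validate_kb()",
         call. = FALSE)
  }
  if (is.null(format)) {
    format <- if (!is.null(path) &&
                  tolower(tools::file_ext(path)) %in% c("yaml", "yml"))
      "yaml" else "json"
  }
  format <- match.arg(format, c("json", "yaml"))
  doc <- kb_to_list(kb)
  txt <- if (format == "json") {
    as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                                  digits = NA))
  } else {
    yaml::as.yaml(doc)
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

kb_to_list <- function(kb) {
  list(
    version = kb$version,
    groups = lapply(seq_len(nrow(kb$groups)), function(i) {
      as.list(kb$groups[i, c("id", "label", "role")])
    }),
    questions = lapply(seq_len(nrow(kb$questions)), function(i) {
      as.list(kb$questions[i, ])
    }),
    rules = unname(lapply(kb$rules, function(r) {
      list(rule_id = r$rule_id, name = r$name, category = r$category,
           outcome_label = r$outcome_label,
           cases = lapply(r$cases, function(cs) {
             list(case_index = cs$case_index,
                  condition = condition_to_list(cs$condition))
           }))
    })),
    recovery_plans = unname(lapply(kb$recovery_plans, function(p) {
      list(injury_key = p$injury_key, label = p$label,
           healing_duration_weeks = p$healing_duration_weeks,
           residual_symptom_horizon_months = p$residual_symptom_horizon_months,
           provisional = p$provisional,
           phases = p$phases)
    })),
    settings = kb$settings
  )
}

#' @export
print.knowledge_base <- function(x, ...) {
  n_cases <- sum(vapply(x$rules, function(r) length(r$cases), 0L))
  cat(sprintf("<knowledge_base v%s>\n", x$version))
  cat(sprintf("  %d groups, %d questions, %d rules (%d cases), %d recovery plans\n",
              nrow(x$groups), nrow(x$questions), length(x$rules), n_cases,
              length(x$recovery_plans)))
  for (r in x$rules) {
    cat(sprintf("  Rule %d (%s): %s\n", r$rule_id, r$category, r$outcome_label))
    for (cs in r$cases) {
      cat(sprintf("    Case %d: %s\n", cs$case_index, format(cs$condition)))
    }
  }
  invisible(x)
}

#' @export
print.recovery_plan <- function(x, ...) {
  cat(sprintf("<recovery_plan %s>%s\n", x$injury_key,
              if (x$provisional) " [provisional]" else ""))
  cat(sprintf("  healing: %d weeks; residual symptoms up to %d months\n",
              x$healing_duration_weeks, x$residual_symptom_horizon_months))
  for (ph in x$phases) {
    cat(sprintf("  weeks %s: %s\n", ph$weeks, ph$instruction))
  }
  invisible(x)
}

# Resolve an inference mode: "strict" turns the printed-table semantics on
# unchanged; "compatibility" enables the exclude_G1_Q6_from_aggregate flag.
apply_mode <- function(kb, mode = NULL) {
  if (is.null(mode)) return(kb)
  mode <- match.arg(mode, c("strict", "compatibility"))
  kb$settings$compatibility_flags$exclude_G1_Q6_from_aggregate <-
    identical(mode, "compatibility")
  kb
}

kb_mode <- function(kb) {
  if (isTRUE(kb$settings$compatibility_flags$exclude_G1_Q6_from_aggregate))
    "compatibility" else "strict"
}

# Diagnostic rules in priority order.
diagnostic_rules <- function(kb) {
  rules <- Filter(function(r) r$category == "diagnostic", kb$rules)
  ids <- vapply(rules, `[[`, 0L, "rule_id")
  rules[match(kb$settings$rule_priority, ids)]
}

# The groups diagnostic classification ranges over: every group except the
# device-eligibility screen, in KB group order. The audit's assignment space
# is total over these even if a contrived rule set references fewer.
diagnostic_groups <- function(kb) {
  kb$groups$id[kb$groups$role != "tens-screen"]
}
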