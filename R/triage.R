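#' Recommend a care path from a determined classification
#'
#' Maps the categorical diagnosis onto the two care paths plus a
#' no-action branch: a likely fracture routes to the clinician (x-ray,
#' casting, supervised TENS), a likely sprain to home care (rest and
#' prescribed exercises), and no injury to no action. The mapping is data,
#' stored in the knowledge base's \code{settings$outcome_paths}, not code.
#' TENS permission is copied from the eligibility screen.
#'
#' @param kb a \code{knowledge_base}
#' @param classification a determined [classify()] result
#' @param eligibility a [tens_eligibility()] result
#' @return object of class \code{triage_recommendation} with \code{path}
#'   (\code{visit-clinician} / \code{home-care} / \code{no-action}),
#'   \code{tens_allowed} (TRUE/FALSE/NA), \code{red_flags} and a
#'   \code{narrative} assembled from knowledge-base strings
#' @export
recommend_path <- function(kb, classification, eligibility) {
  stopifnot(inherits(classification, "classification"))
  if (classification$status != "determined") {
    blk <- unique(classification$blocking$group)
    stop(sprintf(
      "cannot recommend a path for an undetermined classification; blocking group(s): %s",
      paste(blk, collapse = ", ")), call. = FALSE)
  }
  eligibility <- match.arg(eligibility,
                           c("cast-allowed", "cast-prohibited", "undetermined"))
  path <- kb$settings$outcome_paths[[classification$outcome_label]]
  if (is.null(path)) {
    stop(sprintf("no care path configured for outcome '%s'",
                 classification$outcome_label), call. = FALSE)
  }
  tens_allowed <- switch(eligibility,
                         "cast-allowed" = TRUE,
                         "cast-prohibited" = FALSE,
                         NA)
  narrative <- paste0(
    classification$outcome_label, ". ",
    switch(path,
      "visit-clinician" = "Visit a clinician for assessment (x-ray, cast application and supervised TENS therapy as indicated).",
      "home-care" = "Rest at home and follow the prescribed exercises; remote follow-up continues through the application.",
      "no-action" = "No care path is required."),
    switch(eligibility,
      "cast-allowed" = " The patient can use the cast.",
      "cast-prohibited" = " The patient cannot use the cast.",
      " Cast/TENS eligibility is not yet determined."))
  structure(list(path = path,
                 tens_allowed = tens_allowed,
                 red_flags = classification$red_flags,
                 narrative = narrative,
                 outcome_label = classification$outcome_label,
                 mode = classification$mode),
            class = "triage_recommendation")
}

#' @export
print.triage_recommendation <- function(x, ...) {
  cat(sprintf("<triage_recommendation> path=%s tens_allowed=%s\n",
              x$path, ifelse(is.na(x$tens_allowed), "undetermined",
                             x$tens_allowed)))
  cat(" ", x$narrative, "\n")
  for (rf in x$red_flags) cat("  red flag:", rf, "\n")
  invisible(x)
}

#' Look up a recovery plan
#'
#' @param kb a \code{knowledge_base}
#' @param injury_key one of the knowledge base's plan keys
#'   (\code{"weber-a"}, \code{"weber-b"}, \code{"sprain"} in the packaged
#'   base). The Weber B plan carries \code{provisional = TRUE}: its timeline
#'   is stored by analogy with Weber A and should be reviewed by a
#'   clinician.
#' @return a \code{recovery_plan}
#' @export
get_recovery_plan <- function(kb, injury_key) {
  plan <- kb$recovery_plans[[injury_key]]
  if (is.null(plan)) {
    stop(sprintf("unknown injury key '%s'; known keys: %s", injury_key,
                 paste(names(kb$recovery_plans), collapse = ", ")),
         call. = FALSE)
  }
  plan
}

#' TENS electrode placement guidance
#'
#' Static, ordered patient-facing instructions for placing the two TENS
#' electrode pads.
#'
#' @return character vector of instructions, in order
#' @export
tens_placement_steps <- function() {
  c("Clean and dry the skin before placing the electrodes.",
    "Place the two electrode pads over or near the area of pain.",
    "Attach the electrodes to the skin, using adhesive if necessary.")
}

#' Pain-report logging
#'
#' A pain log records follow-up self-reports (0--10 pain score, TENS
#' intensity as an opaque ordinal, and whether the patient stopped the
#' therapy) plus the emergency-stop events derived from them. Stopping TENS
#' therapy is the event clinicians are notified about, so an
#' emergency-stop event is emitted exactly when a report has
#' \code{stopped = TRUE}.
#'
#' @return \code{pain_log()} returns an empty log (class \code{pain_log})
#' @export
pain_log <- function() {
  structure(list(
    reports = data.frame(timestamp = numeric(0), score = integer(0),
                         tens_intensity = integer(0), stopped = logical(0)),
    events = data.frame(timestamp = numeric(0), score = integer(0),
                        stringsAsFactors = FALSE)),
    class = "pain_log")
}

#' @rdname pain_log
#' @param log a \code{pain_log}
#' @param score integer pain score in 0--10
#' @param stopped did the patient stop TENS therapy?
#' @param tens_intensity opaque ordinal device level
#' @param timestamp numeric time; defaults to one past the previous report
#'   so logs built in code are totally ordered
#' @export
record_pain_report <- function(log, score, stopped = FALSE,
                               tens_intensity = NA_integer_,
                               timestamp = NULL) {
  stopifnot(inherits(log, "pain_log"))
  if (!is.finite(score) || score != as.integer(score) ||
      score < 0 || score > 10) {
    stop("pain score must be an integer between 0 and 10", call. = FALSE)
  }
  if (is.null(timestamp)) {
    timestamp <- if (nrow(log$reports)) max(log$reports$timestamp) + 1 else 1
  }
  if (nrow(log$reports) && timestamp <= max(log$reports$timestamp)) {
    stop("report timestamps must be strictly increasing", call. = FALSE)
  }
  log$reports <- rbind(log$reports, data.frame(
    timestamp = as.numeric(timestamp), score = as.integer(score),
    tens_intensity = as.integer(tens_intensity), stopped = isTRUE(stopped)))
  if (isTRUE(stopped)) {
    log$events <- rbind(log$events, data.frame(
      timestamp = as.numeric(timestamp), score = as.integer(score)))
  }
  log
}

#' @rdname pain_log
#' @details \code{pain_trend()} is descriptive only: latest score, mean
#'   score, and the ordinary-least-squares slope of score over time
#'   (\code{NA} with fewer than two reports).
#' @export
pain_trend <- function(log) {
  stopifnot(inherits(log, "pain_log"))
  if (nrow(log$reports) == 0L) stop("pain log is empty", call. = FALSE)
  r <- log$reports
  slope <- if (nrow(r) >= 2L) {
    unname(stats::coef(stats::lm(score ~ timestamp, data = r))[2])
  } else {
    NA_real_
  }
  list(latest = r$score[nrow(r)], mean = mean(r$score), slope = slope,
       n = nrow(r))
}

#' @export
print.pain_log <- function(x, ...) {
  cat(sprintf("<pain_log> %d report(s), %d emergency-stop event(s)\n",
              nrow(x$reports), nrow(x$events)))
  invisible(x)
}
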