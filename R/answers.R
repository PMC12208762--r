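#' Construct a patient answer set
#'
#' An answer set holds a patient's (possibly partial) questionnaire
#' responses plus the body metrics needed for the BMI sub-computation.
#' Unanswered questions are simply absent from \code{responses}.
#'
#' @param responses named character vector or list mapping question id to
#'   \code{"yes"} or \code{"no"}
#' @param sex \code{"female"}, \code{"male"} or \code{"unspecified"};
#'   female-only questions are auto-resolved to "no finding" for non-female
#'   patients
#' @param weight_kg body mass in kilograms, or \code{NA} if not provided
#' @param height_cm height in centimeters, or \code{NA} if not provided
#' @return an object of class \code{answer_set}
#' @examples
#' answer_set(c(G1.Q1 = "no", G2.Q1 = "yes"), sex = "male")
#' @export
answer_set <- function(responses = character(0), sex = "unspecified",
                       weight_kg = NA_real_, height_cm = NA_real_) {
  sex <- match.arg(sex, c("female", "male", "unspecified"))
  responses <- unlist(responses)
  if (length(responses)) {
    responses <- vapply(responses, as.character, "")
    bad <- !responses %in% c("yes", "no")
    if (any(bad)) {
      stop(sprintf("responses must be 'yes' or 'no'; got '%s' for %s",
                   responses[bad][1], names(responses)[bad][1]), call. = FALSE)
    }
    if (is.null(names(responses)) || any(!nzchar(names(responses)))) {
      stop("every response must be named by its question id", call. = FALSE)
    }
    if (anyDuplicated(names(responses))) {
      stop("duplicate question id in responses", call. = FALSE)
    }
  } else {
    responses <- stats::setNames(character(0), character(0))
  }
  weight_kg <- as.numeric(weight_kg)
  height_cm <- as.numeric(height_cm)
  if (length(weight_kg) != 1L) weight_kg <- NA_real_
  if (length(height_cm) != 1L) height_cm <- NA_real_
  if (!is.na(weight_kg) && weight_kg <= 0) stop("weight_kg must be positive", call. = FALSE)
  if (!is.na(height_cm) && height_cm <= 0) stop("height_cm must be positive", call. = FALSE)
  structure(list(sex = sex, responses = responses,
                 weight_kg = weight_kg, height_cm = height_cm),
            class = "answer_set")
}

# Response for one question id, NA_character_ when unanswered.
get_response <- function(answers, id) {
  if (id %in% names(answers$responses)) answers$responses[[id]] else NA_character_
}

# Error if an answer set references question ids unknown to the KB.
check_answers <- function(kb, answers) {
  stopifnot(inherits(answers, "answer_set"))
  unknown <- setdiff(names(answers$responses), kb$questions$id)
  if (length(unknown)) {
    stop(sprintf("answer set references unknown question id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  invisible(answers)
}

#' @export
print.answer_set <- function(x, ...) {
  cat(sprintf("<answer_set> sex=%s, weight=%s kg, height=%s cm, %d response(s)\n",
              x$sex,
              ifelse(is.na(x$weight_kg), "?", format(x$weight_kg)),
              ifelse(is.na(x$height_cm), "?", format(x$height_cm)),
              length(x$responses)))
  if (length(x$responses)) {
    for (q in names(x$responses)) cat(sprintf("  %s: %s\n", q, x$responses[[q]]))
  }
  invisible(x)
}

#' Read and write answer files
#'
#' Two dialects are supported. JSON: an object with keys \code{sex},
#' \code{weight_kg}, \code{height_cm} and \code{responses} (question id to
#' "yes"/"no"); a JSON array of such objects holds several patients. CSV:
#' one row per patient with columns \code{sex}, \code{weight_kg},
#' \code{height_cm} and one column per question id, empty cells meaning
#' unanswered.
#'
#' @param path file to read or write
#' @return \code{read_answers} returns a list of \code{answer_set} (a
#'   single-patient JSON file still yields a length-one list)
#' @export
read_answers <- function(path) {
  if (!file.exists(path)) stop(sprintf("answer file not found: '%s'", path), call. = FALSE)
  if (tolower(tools::file_ext(path)) == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
    return(lapply(seq_len(nrow(df)), function(i) answers_from_row(df[i, , drop = FALSE])))
  }
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(x$responses) || !is.null(x$sex)) x <- list(x)
  lapply(x, function(rec) {
    answer_set(responses = unlist(rec$responses) %||% character(0),
               sex = rec$sex %||% "unspecified",
               weight_kg = rec$weight_kg %||% NA_real_,
               height_cm = rec$height_cm %||% NA_real_)
  })
}

answers_from_row <- function(row) {
  meta <- c("id", "sex", "weight_kg", "height_cm")
  qcols <- setdiff(names(row), meta)
  vals <- unlist(row[1, qcols, drop = TRUE])
  vals <- vals[!is.na(vals) & nzchar(vals)]
  num_or_na <- function(v) {
    if (is.null(v) || is.na(v) || !nzchar(v)) NA_real_ else as.numeric(v)
  }
  answer_set(responses = vals,
             sex = if ("sex" %in% names(row) && nzchar(row$sex)) row$sex else "unspecified",
             weight_kg = num_or_na(row$weight_kg),
             height_cm = num_or_na(row$height_cm))
}

#' @rdname read_answers
#' @param answers a list of \code{answer_set} (or a single one)
#' @param kb knowledge base supplying the full question-column order for CSV
#' @param format "json" or "csv"; inferred from the extension by default
#' @export
write_answers <- function(answers, path, kb = ankle_kb(), format = NULL) {
  if (inherits(answers, "answer_set")) answers <- list(answers)
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  }
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") {
    recs <- lapply(answers, function(a) {
      rec <- list(sex = a$sex,
                  weight_kg = if (is.na(a$weight_kg)) NULL else a$weight_kg,
                  height_cm = if (is.na(a$height_cm)) NULL else a$height_cm,
                  responses = as.list(a$responses))
      Filter(Negate(is.null), rec)
    })
    if (length(recs) == 1L) recs <- recs[[1]]
    writeLines(as.character(jsonlite::toJSON(recs, auto_unbox = TRUE,
                                             pretty = TRUE, digits = NA)), path)
  } else {
    qids <- kb$questions$id
    rows <- lapply(seq_along(answers), function(i) {
      a <- answers[[i]]
      vals <- stats::setNames(rep("", length(qids)), qids)
      vals[names(a$responses)] <- a$responses
      c(id = as.character(i), sex = a$sex,
        weight_kg = if (is.na(a$weight_kg)) "" else format(a$weight_kg, digits = 15),
        height_cm = if (is.na(a$height_cm)) "" else format(a$height_cm, digits = 15),
        vals)
    })
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE,
                        check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
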