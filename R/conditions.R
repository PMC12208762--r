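#' Condition expressions over question-group findings
#'
#' Rule antecedents are finite expression trees whose leaves test the
#' aggregate finding of one question group and whose internal nodes are
#' logical connectives. Two leaf forms exist, mirroring the two aggregate
#' tests used by the clinical rule table:
#' \itemize{
#'   \item \code{any_positive(g)} -- at least one question in group \code{g}
#'     has its positive clinical finding ("yes in any").
#'   \item \code{none_positive(g)} -- no question in group \code{g} has its
#'     positive finding ("no in all"); logically the negation of
#'     \code{any_positive(g)}.
#' }
#'
#' @param group single group id, e.g. \code{"G2"}
#' @return a condition node (a list with class \code{"kb_condition"})
#' @examples
#' cnd_and(none_positive("G1"), any_positive("G2"))
#' @name conditions
NULL

new_condition <- function(x) {
  class(x) <- "kb_condition"
  x
}

#' @rdname conditions
#' @export
any_positive <- function(group) {
  stopifnot(is.character(group), length(group) == 1L)
  new_condition(list(op = "any", group = group))
}

#' @rdname conditions
#' @export
none_positive <- function(group) {
  stopifnot(is.character(group), length(group) == 1L)
  new_condition(list(op = "none", group = group))
}

#' @rdname conditions
#' @param ... child condition nodes
#' @export
cnd_and <- function(...) {
  args <- list(...)
  stopifnot(length(args) >= 1L)
  new_condition(list(op = "and", args = args))
}

#' @rdname conditions
#' @export
cnd_or <- function(...) {
  args <- list(...)
  stopifnot(length(args) >= 1L)
  new_condition(list(op = "or", args = args))
}

# Structural check; returns character vector of problems ("" path = root).
check_condition <- function(cond, group_ids, path = "condition") {
  if (!is.list(cond) || is.null(cond$op)) {
    return(sprintf("%s: not a condition node", path))
  }
  switch(cond$op,
    any = ,
    none = {
      if (is.null(cond$group) || !is.character(cond$group) || length(cond$group) != 1L) {
        sprintf("%s: leaf missing 'group'", path)
      } else if (!cond$group %in% group_ids) {
        sprintf("%s: references undefined group '%s'", path, cond$group)
      } else {
        character(0)
      }
    },
    and = ,
    or = {
      if (is.null(cond$args) || length(cond$args) == 0L) {
        sprintf("%s: '%s' node with no arguments", path, cond$op)
      } else {
        unlist(lapply(seq_along(cond$args), function(i) {
          check_condition(cond$args[[i]], group_ids,
                          sprintf("%s.args[%d]", path, i))
        }))
      }
    },
    sprintf("%s: unknown operator '%s'", path, cond$op)
  )
}

# All group ids referenced by a condition tree.
condition_groups <- function(cond) {
  switch(cond$op,
    any = ,
    none = cond$group,
    unique(unlist(lapply(cond$args, condition_groups)))
  )
}

#' Format a condition in the rule table's own notation
#'
#' @param x condition node
#' @param ... ignored
#' @return single character string such as
#'   \code{"(no in all G1) AND (yes in any of G2)"}
#' @export
format.kb_condition <- function(x, ...) {
  fmt <- function(cond, top = FALSE) {
    switch(cond$op,
      any = sprintf("(yes in any of %s)", cond$group),
      none = sprintf("(no in all %s)", cond$group),
      and = {
        s <- paste(vapply(cond$args, fmt, ""), collapse = " AND ")
        if (top) s else paste0("(", s, ")")
      },
      or = {
        s <- paste(vapply(cond$args, fmt, ""), collapse = " OR ")
        if (top) s else paste0("(", s, ")")
      }
    )
  }
  fmt(x, top = TRUE)
}

#' @export
print.kb_condition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Plain-list form for serialization (drops the S3 class recursively).
condition_to_list <- function(cond) {
  if (cond$op %in% c("any", "none")) {
    list(op = cond$op, group = cond$group)
  } else {
    list(op = cond$op, args = lapply(cond$args, condition_to_list))
  }
}

condition_from_list <- function(x) {
  if (!is.list(x) || is.null(x$op)) stop("malformed condition node", call. = FALSE)
  if (x$op %in% c("any", "none")) {
    new_condition(list(op = x$op, group = as.character(x$group)))
  } else if (x$op %in% c("and", "or")) {
    new_condition(list(op = x$op, args = lapply(x$args, condition_from_list)))
  } else {
    stop(sprintf("unknown condition operator '%s'", x$op), call. = FALSE)
  }
}
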