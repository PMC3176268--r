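#' Value domains for experimental variables
#'
#' A value domain describes the admissible values of a variable node
#' (parameter, constant or measurement) in an experimental-design model.
#' Five kinds are supported: `nominal` (unordered category labels),
#' `ordinal` (category labels in a fixed total order), `free_text`,
#' `region_extent` (a qualified spatial description resolved against a brain
#' atlas, see [region_extent()]) and `numeric` (with optional units).
#'
#' @param kind One of `"nominal"`, `"ordinal"`, `"free_text"`,
#'   `"region_extent"`, `"numeric"`.
#' @param levels Character vector of category labels; required for nominal
#'   and ordinal domains.  For ordinal domains the vector order *is* the
#'   scale order.
#' @param units Optional unit string for numeric domains.
#' @return An object of class `kefed_domain`.
#' @examples
#' value_domain("ordinal", levels = c("low", "medium", "high"))
#' value_domain("numeric", units = "mm")
#' @export
value_domain <- function(kind, levels = NULL, units = NULL) {
  kinds <- c("nominal", "ordinal", "free_text", "region_extent", "numeric")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    stop("domain kind must be one of: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(levels)) levels <- as.character(levels)
  dom <- structure(list(kind = kind, levels = levels, units = units),
                   class = "kefed_domain")
  dom
}

# Returns character vector of problems, empty if well-formed.
domain_problems <- function(dom) {
  if (!inherits(dom, "kefed_domain")) return("not a value domain object")
  probs <- character()
  if (dom$kind %in% c("nominal", "ordinal")) {
    if (is.null(dom$levels) || length(dom$levels) == 0L)
      probs <- c(probs, sprintf("%s domain has no levels", dom$kind))
    else {
      if (anyDuplicated(dom$levels))
        probs <- c(probs, sprintf("%s domain has duplicate levels", dom$kind))
      if (dom$kind == "ordinal" && length(unique(dom$levels)) < 2L)
        probs <- c(probs, "ordinal domain needs >= 2 distinct ordered levels")
    }
  } else if (!is.null(dom$levels)) {
    probs <- c(probs, sprintf("%s domain must not declare levels", dom$kind))
  }
  probs
}

#' Check a single value against a value domain
#'
#' @param dom A [value_domain()].
#' @param value The candidate value.
#' @return `TRUE` if the value is admissible, otherwise a string describing
#'   the violation.
#' @export
domain_check <- function(dom, value) {
  stopifnot(inherits(dom, "kefed_domain"))
  switch(dom$kind,
    nominal = ,
    ordinal = {
      if (is.character(value) && length(value) == 1L && value %in% dom$levels)
        TRUE
      else sprintf("value %s not among levels {%s}",
                   deparse1(value), paste(dom$levels, collapse = ", "))
    },
    free_text = {
      if (is.character(value) && length(value) == 1L) TRUE
      else "free-text value must be a single string"
    },
    numeric = {
      if (is.numeric(value) && length(value) == 1L && is.finite(value)) TRUE
      else "numeric value must be a single finite number"
    },
    region_extent = {
      if (inherits(value, "region_extent")) TRUE
      else if (is.character(value) && length(value) == 1L &&
               !inherits(try(parse_extent(value), silent = TRUE), "try-error"))
        TRUE
      else "value is not a region extent or a parseable extent expression"
    })
}

#' @export
print.kefed_domain <- function(x, ...) {
  sep <- if (x$kind == "ordinal") " < " else ", "
  cat("<domain:", x$kind, ">", sep = "")
  if (!is.null(x$levels)) cat(" ", paste(x$levels, collapse = sep), sep = "")
  if (!is.null(x$units)) cat(" [", x$units, "]", sep = "")
  cat("\n")
  invisible(x)
}
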