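EXTENT_RELATIONS <- c("coextensive_with", "proper_part_of", "overlaps")

#' Qualified spatial extents of injection sites and labeling
#'
#' Tract-tracing reports rarely describe an injection site or a patch of
#' labeling as exactly one named structure.  A region extent expresses an
#' arbitrarily drawn region through qualified relations to named atlas
#' regions: the extent may be `coextensive_with` a region, a
#' `proper_part_of` a region, or it may `overlaps` a region (covering part
#' of it plus territory outside it).  Several assertions may be combined,
#' e.g. a tracer deposit that overlapped two adjacent areas.
#'
#' @param relations Character vector of relations, each one of
#'   `coextensive_with`, `proper_part_of`, `overlaps`.
#' @param regions Character vector of region abbreviations, same length.
#' @param free_label Optional free-text description.
#' @return An object of class `region_extent`.
#' @examples
#' region_extent("coextensive_with", "CA1")
#' parse_extent("overlaps(ENT)|overlaps(PRC)")
#' @export
region_extent <- function(relations, regions, free_label = NULL) {
  relations <- as.character(relations)
  regions <- as.character(regions)
  if (length(relations) != length(regions) || length(relations) == 0L)
    stop("a region extent needs >= 1 (relation, region) assertion",
         call. = FALSE)
  if (!all(relations %in% EXTENT_RELATIONS))
    stop("unknown extent relation(s): ",
         paste(setdiff(relations, EXTENT_RELATIONS), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(regions)))
    stop("extent region abbreviations must be non-empty", call. = FALSE)
  structure(list(assertions = data.frame(relation = relations,
                                         region = regions,
                                         stringsAsFactors = FALSE),
                 free_label = free_label),
            class = "region_extent")
}

#' Parse and format the flat extent expression grammar
#'
#' Extents are serialized in table cells as `rel(ABBREV)` terms joined by
#' `|`, e.g. `part_of(ENTl)|overlaps(PRC)`.  Accepted relation tokens are
#' `coextensive_with` (alias `coext`), `proper_part_of` (alias `part_of`)
#' and `overlaps`.
#'
#' @param x A single expression string (`parse_extent`) or a
#'   `region_extent` (`format_extent`).
#' @return `parse_extent()` returns a [region_extent()]; `format_extent()`
#'   its canonical string form.
#' @export
parse_extent <- function(x) {
  if (inherits(x, "region_extent")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  terms <- strsplit(trimws(x), "|", fixed = TRUE)[[1]]
  terms <- trimws(terms)
  if (!length(terms) || any(!nzchar(terms)))
    stop("empty extent expression", call. = FALSE)
  m <- regmatches(terms, regexec("^([A-Za-z_]+)\\(([^()]+)\\)$", terms))
  rels <- character(length(terms)); regs <- character(length(terms))
  for (i in seq_along(terms)) {
    if (length(m[[i]]) != 3L)
      stop(sprintf("cannot parse extent term '%s' (expected rel(ABBREV))",
                   terms[i]), call. = FALSE)
    tok <- m[[i]][2]
    rels[i] <- switch(tok,
      coextensive_with = , coext = "coextensive_with",
      proper_part_of = , part_of = "proper_part_of",
      overlaps = "overlaps",
      stop(sprintf("unknown extent relation '%s'", tok), call. = FALSE))
    regs[i] <- trimws(m[[i]][3])
  }
  region_extent(rels, regs)
}

#' @rdname parse_extent
#' @export
format_extent <- function(x) {
  stopifnot(inherits(x, "region_extent"))
  tok <- c(coextensive_with = "coextensive_with",
           proper_part_of = "part_of", overlaps = "overlaps")
  paste(sprintf("%s(%s)", tok[x$assertions$relation], x$assertions$region),
        collapse = "|")
}

#' @export
print.region_extent <- function(x, ...) {
  cat("<extent>", format_extent(x), "\n")
  invisible(x)
}

#' @export
format.region_extent <- function(x, ...) format_extent(x)

#' @export
as.character.region_extent <- function(x, ...) format_extent(x)

extent_equal <- function(a, b) {
  norm <- function(e) {
    df <- e$assertions[order(e$assertions$relation, e$assertions$region), ]
    rownames(df) <- NULL
    df
  }
  identical(norm(a), norm(b))
}
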