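#' Brain-region atlases with qualitative spatial relations
#'
#' An atlas is a set of named regions together with two qualitative
#' relations: `proper_part_of`, an irreflexive containment relation whose
#' transitive closure must be acyclic (the parcellation hierarchy), and
#' `overlaps`, a symmetric irreflexive relation between regions that share
#' territory while each extending beyond the other.  All reasoning
#' operations ([is_part_of()], [part_of_or_overlaps()], [resolve_extent()])
#' work over these two relations only; no metric geometry is involved.
#'
#' @param regions Data frame with columns `abbrev`, `name`, `source` (or a
#'   character vector of abbreviations).
#' @param part_of Data frame with columns `child`, `parent`.
#' @param overlaps Data frame with columns `a`, `b`; stored normalized with
#'   `a < b`, so asserting either direction is equivalent.
#' @return An object of class `brain_atlas`.
#' @examples
#' demo_atlas()
#' @export
brain_atlas <- function(regions,
                        part_of = data.frame(child = character(),
                                             parent = character()),
                        overlaps = data.frame(a = character(),
                                              b = character())) {
  if (is.character(regions))
    regions <- data.frame(abbrev = regions, name = regions, source = "",
                          stringsAsFactors = FALSE)
  stopifnot(is.data.frame(regions), all(c("abbrev") %in% names(regions)))
  if (is.null(regions$name)) regions$name <- regions$abbrev
  if (is.null(regions$source)) regions$source <- ""
  regions <- regions[, c("abbrev", "name", "source")]
  regions$abbrev <- as.character(regions$abbrev)
  if (any(!nzchar(regions$abbrev)))
    stop("region abbreviations must be non-empty", call. = FALSE)
  if (anyDuplicated(regions$abbrev))
    stop("duplicate region abbreviation(s): ",
         paste(unique(regions$abbrev[duplicated(regions$abbrev)]),
               collapse = ", "), call. = FALSE)
  regions <- regions[order(regions$abbrev), ]
  rownames(regions) <- NULL

  part_of <- data.frame(child = as.character(part_of$child),
                        parent = as.character(part_of$parent),
                        stringsAsFactors = FALSE)
  part_of <- unique(part_of)
  overlaps <- data.frame(a = as.character(overlaps$a),
                         b = as.character(overlaps$b),
                         stringsAsFactors = FALSE)
  # normalize unordered pairs
  if (nrow(overlaps)) {
    swap <- overlaps$a > overlaps$b
    tmp <- overlaps$a[swap]
    overlaps$a[swap] <- overlaps$b[swap]
    overlaps$b[swap] <- tmp
    overlaps <- unique(overlaps)
  }

  known <- regions$abbrev
  refs <- c(part_of$child, part_of$parent, overlaps$a, overlaps$b)
  if (!all(refs %in% known))
    stop("relation references undeclared region(s): ",
         paste(unique(setdiff(refs, known)), collapse = ", "), call. = FALSE)
  if (any(part_of$child == part_of$parent))
    stop("proper_part_of is irreflexive; offending region(s): ",
         paste(unique(part_of$child[part_of$child == part_of$parent]),
               collapse = ", "), call. = FALSE)
  if (any(overlaps$a == overlaps$b))
    stop("overlaps is irreflexive", call. = FALSE)
  cyc <- cycle_members(part_of$child, part_of$parent)
  if (length(cyc))
    stop("containment cycle among regions: ", paste(cyc, collapse = ", "),
         call. = FALSE)

  part_of <- part_of[order(part_of$child, part_of$parent), , drop = FALSE]
  overlaps <- overlaps[order(overlaps$a, overlaps$b), , drop = FALSE]
  rownames(part_of) <- rownames(overlaps) <- NULL
  structure(list(regions = regions, part_of = part_of, overlaps = overlaps),
            class = "brain_atlas")
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat(sprintf("<brain_atlas> %d regions, %d containment pairs, %d overlap pairs\n",
              nrow(x$regions), nrow(x$part_of), nrow(x$overlaps)))
  invisible(x)
}

check_region <- function(atlas, ...) {
  abbrevs <- c(...)
  missing <- setdiff(abbrevs, atlas$regions$abbrev)
  if (length(missing))
    stop("unknown region(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Transitive proper parthood between regions
#'
#' `TRUE` iff `sub` lies in the transitive closure of the containment
#' relation below `super`.  Proper parthood is irreflexive:
#' `is_part_of(a, x, x)` is `FALSE`.
#'
#' @param atlas A [brain_atlas()].
#' @param sub,super Region abbreviations.
#' @return Logical scalar.
#' @examples
#' is_part_of(demo_atlas(), "RSPv-a", "RSP")
#' @export
is_part_of <- function(atlas, sub, super) {
  stopifnot(inherits(atlas, "brain_atlas"))
  check_region(atlas, sub, super)
  if (sub == super) return(FALSE)
  !is.null(containment_path(atlas, sub, super))
}

# BFS upward through parents; returns the abbrev chain sub, ..., super or
# NULL when unreachable.  Deterministic: parents explored in sorted order.
containment_path <- function(atlas, sub, super) {
  po <- atlas$part_of
  prev <- stats::setNames(list(NULL), sub)
  frontier <- sub
  while (length(frontier)) {
    nxt <- character()
    for (r in frontier) {
      for (p in sort(po$parent[po$child == r])) {
        if (!p %in% names(prev)) {
          prev[[p]] <- r
          nxt <- c(nxt, p)
        }
      }
    }
    if (super %in% names(prev)) {
      path <- super
      while (!is.null(prev[[path[1]]])) path <- c(prev[[path[1]]], path)
      return(path)
    }
    frontier <- nxt
  }
  NULL
}

#' All strict descendants of a region
#' @inheritParams is_part_of
#' @param region Region abbreviation.
#' @return Character vector of abbreviations `r` with `is_part_of(r, region)`.
#' @export
region_descendants <- function(atlas, region) {
  stopifnot(inherits(atlas, "brain_atlas"))
  check_region(atlas, region)
  po <- atlas$part_of
  out <- character(); frontier <- region
  while (length(frontier)) {
    kids <- unique(po$child[po$parent %in% frontier])
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  sort(out)
}

# strict ancestors, sorted
region_ancestors <- function(atlas, region) {
  po <- atlas$part_of
  out <- character(); frontier <- region
  while (length(frontier)) {
    pars <- unique(po$parent[po$child %in% frontier])
    pars <- setdiff(pars, out)
    out <- c(out, pars)
    frontier <- pars
  }
  sort(out)
}

# top-level region(s) enclosing `region` (itself if it has no parent)
region_roots <- function(atlas, region) {
  anc <- c(region, region_ancestors(atlas, region))
  has_parent <- anc %in% atlas$part_of$child
  sort(anc[!has_parent])
}

atlas_overlaps <- function(atlas, x, y) {
  ov <- atlas$overlaps
  any((ov$a == x & ov$b == y) | (ov$a == y & ov$b == x))
}

overlap_partners <- function(atlas, x) {
  ov <- atlas$overlaps
  sort(unique(c(ov$b[ov$a == x], ov$a[ov$b == x])))
}
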