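GEO_VERDICTS <- c("identical", "contained", "overlap", "overlap_of_part",
                  "none")

geo_trail <- function(verdict, relation = character(), from = character(),
                      to = character()) {
  structure(list(verdict = verdict,
                 steps = data.frame(relation = relation, from = from,
                                    to = to, stringsAsFactors = FALSE)),
            class = "geo_trail")
}

#' @export
print.geo_trail <- function(x, ...) {
  cat("<geo_trail>", x$verdict)
  if (nrow(x$steps))
    cat(":", paste(sprintf("%s(%s,%s)", x$steps$relation, x$steps$from,
                           x$steps$to), collapse = " & "))
  cat("\n")
  invisible(x)
}

trail_summary <- function(trail) {
  if (nrow(trail$steps) == 0) return(trail$verdict)
  paste0(trail$verdict, ": ",
         paste(sprintf("%s(%s,%s)", trail$steps$relation, trail$steps$from,
                       trail$steps$to), collapse = " & "))
}

steps_for_containment <- function(path) {
  # path = c(sub, ..., super)
  data.frame(relation = rep("proper_part_of", length(path) - 1L),
             from = path[-length(path)], to = path[-1L],
             stringsAsFactors = FALSE)
}

#' Combined containment-or-overlap query between two regions
#'
#' The workhorse relation of the qualitative spatial layer.
#' `part_of_or_overlaps(atlas, sub, super)` holds iff any of four
#' conditions does, tried in this fixed order so reasoning trails are
#' deterministic:
#'
#' 1. `sub` and `super` are the same region (*identical*);
#' 2. `sub` is a proper part of `super`, transitively (*contained*);
#' 3. `sub` overlaps `super` directly (*overlap*);
#' 4. some region is a proper part of `super` and `sub` overlaps that
#'    region (*overlap_of_part*).
#'
#' Overlap is deliberately not propagated any further than the single
#' containment hop in condition 4.
#'
#' @inheritParams is_part_of
#' @return List with elements `result` (logical) and `trail`, a `geo_trail`
#'   whose `verdict` names the condition that fired (`none` when false) and
#'   whose `steps` record the relation instances used, replayable with
#'   [replay_trail()].
#' @examples
#' a <- demo_atlas()
#' part_of_or_overlaps(a, "RSPv-a", "RSP")$trail
#' @export
part_of_or_overlaps <- function(atlas, sub, super) {
  stopifnot(inherits(atlas, "brain_atlas"))
  check_region(atlas, sub, super)
  if (sub == super) {
    return(list(result = TRUE,
                trail = geo_trail("identical", "identity", sub, super)))
  }
  path <- containment_path(atlas, sub, super)
  if (!is.null(path)) {
    st <- steps_for_containment(path)
    return(list(result = TRUE,
                trail = geo_trail("contained", st$relation, st$from, st$to)))
  }
  if (atlas_overlaps(atlas, sub, super)) {
    return(list(result = TRUE,
                trail = geo_trail("overlap", "overlaps", sub, super)))
  }
  # condition 4: first witness in sorted order for a deterministic trail
  for (r in overlap_partners(atlas, sub)) {
    path <- containment_path(atlas, r, super)
    if (!is.null(path)) {
      st <- rbind(data.frame(relation = "overlaps", from = sub, to = r,
                             stringsAsFactors = FALSE),
                  steps_for_containment(path))
      return(list(result = TRUE,
                  trail = geo_trail("overlap_of_part", st$relation,
                                    st$from, st$to)))
    }
  }
  list(result = FALSE, trail = geo_trail("none"))
}

#' Replay a reasoning trail against an atlas
#'
#' Verifies that every step of a [part_of_or_overlaps()] /
#' [resolve_extent()] trail uses a relation instance actually present in
#' the atlas (containment steps must be declared pairs, overlap steps
#' declared overlaps) and that the steps support the recorded verdict.
#'
#' @inheritParams is_part_of
#' @param trail A `geo_trail`.
#' @return Logical: does the trail replay?
#' @export
replay_trail <- function(atlas, trail) {
  stopifnot(inherits(trail, "geo_trail"))
  st <- trail$steps
  for (i in seq_len(nrow(st))) {
    ok <- switch(st$relation[i],
      identity = st$from[i] == st$to[i],
      proper_part_of = any(atlas$part_of$child == st$from[i] &
                             atlas$part_of$parent == st$to[i]),
      # "<extent>" marks the drawn extent itself: its overlap with a named
      # region is a data assertion, not an atlas relation
      overlaps = st$from[i] == "<extent>" ||
        atlas_overlaps(atlas, st$from[i], st$to[i]),
      extent_assertion = TRUE,
      FALSE)
    if (!ok) return(FALSE)
  }
  if (trail$verdict == "none") return(nrow(st) == 0)
  nrow(st) > 0
}

# Rank verdicts from most to least direct; used to keep the strongest
# match when several extent assertions fire.
verdict_rank <- function(v) match(v, GEO_VERDICTS)

#' Match a drawn extent against a named target region
#'
#' Decides whether an injection-site or labeling extent (a set of qualified
#' relations to named regions, see [region_extent()]) provides evidence at
#' the named target region, and how direct that evidence is.  Each
#' assertion `rel(N)` is tested:
#'
#' * `coextensive_with(N)`: the extent *is* `N`, so the match is exactly
#'   [part_of_or_overlaps()] of `N` against the target (`identical` when
#'   `N` is the target itself).
#' * `proper_part_of(N)`: the extent lies inside `N`; it is *contained* in
#'   the target when `N` is the target or a part of it, and counts as
#'   overlap-grade evidence when `N` merely overlap-relates to the target.
#' * `overlaps(N)`: the extent pokes into `N`; it overlaps the target when
#'   `N` is the target, overlaps a part of the target when `N` is a proper
#'   part of it, and is kept as weakest overlap-grade evidence when `N`
#'   itself overlaps the target.
#'
#' When several assertions match, the most direct verdict wins
#' (identical > contained > overlap > overlap_of_part).
#'
#' @inheritParams is_part_of
#' @param extent A [region_extent()] or extent expression string.
#' @param target Region abbreviation.
#' @return List with `result` (logical), `trail` (a `geo_trail` for the
#'   best match; verdict `none` when no assertion matches).
#' @examples
#' a <- demo_atlas()
#' resolve_extent(a, "coextensive_with(RSPv-a)", "RSP")
#' @export
resolve_extent <- function(atlas, extent, target) {
  stopifnot(inherits(atlas, "brain_atlas"))
  extent <- parse_extent(extent)
  check_region(atlas, target)
  check_region(atlas, extent$assertions$region)

  best <- geo_trail("none")
  consider <- function(verdict, assertion_i, inner_steps) {
    if (verdict_rank(verdict) < verdict_rank(best$verdict)) {
      pre <- data.frame(relation = "extent_assertion",
                        from = sprintf("%s(%s)",
                                       extent$assertions$relation[assertion_i],
                                       extent$assertions$region[assertion_i]),
                        to = target, stringsAsFactors = FALSE)
      best <<- geo_trail(verdict, c(pre$relation, inner_steps$relation),
                         c(pre$from, inner_steps$from),
                         c(pre$to, inner_steps$to))
    }
  }

  for (i in seq_len(nrow(extent$assertions))) {
    rel <- extent$assertions$relation[i]
    n <- extent$assertions$region[i]
    poo <- part_of_or_overlaps(atlas, n, target)
    if (rel == "coextensive_with") {
      if (poo$result) consider(poo$trail$verdict, i, poo$trail$steps)
    } else if (rel == "proper_part_of") {
      if (poo$result) {
        v <- if (poo$trail$verdict %in% c("identical", "contained"))
          "contained" else poo$trail$verdict
        consider(v, i, poo$trail$steps)
      }
    } else {  # overlaps(N): the extent itself plays the sub role
      if (n == target) {
        consider("overlap",
                 i, data.frame(relation = "overlaps", from = "<extent>",
                               to = n, stringsAsFactors = FALSE))
      } else {
        path <- containment_path(atlas, n, target)
        if (!is.null(path)) {
          st <- rbind(data.frame(relation = "overlaps", from = "<extent>",
                                 to = n, stringsAsFactors = FALSE),
                      steps_for_containment(path))
          consider("overlap_of_part", i, st)
        } else if (atlas_overlaps(atlas, n, target)) {
          consider("overlap_of_part", i,
                   data.frame(relation = c("overlaps", "overlaps"),
                              from = c("<extent>", n), to = c(n, target),
                              stringsAsFactors = FALSE))
        }
      }
    }
  }
  list(result = best$verdict != "none", trail = best)
}
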