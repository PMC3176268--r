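STRENGTH_LEVELS <- c("none", "weak", "moderate", "strong")

#' The seven-point labeling-density scale
#'
#' Ordered categories for reported histological labeling density, from
#' `no label` to `dense label`, plus the extra category `present-unknown`
#' for reports that state labeling is present without grading its density.
#'
#' @return Character vector of the 7 ordered labels (and the extra category
#'   appended when `with_unknown`).
#' @param with_unknown Include the `present-unknown` category?
#' @export
density_levels <- function(with_unknown = TRUE) {
  lv <- c("no label", "very sparse label", "sparse label",
          "sparse/moderate label", "moderate label", "moderate/dense label",
          "dense label")
  if (with_unknown) c(lv, "present-unknown") else lv
}

#' Registry of tracer transport directions
#'
#' Interpreting a tract-tracing observation requires background knowledge
#' of how each tracer chemical travels: anterograde tracers move from cell
#' bodies to axon terminals, retrograde tracers from axon fibers back to
#' the cell bodies.  Every chemical appearing in a dataset must be
#' registered before interpretation.
#'
#' @param directions Named character vector, `chemical -> direction`, each
#'   direction `"anterograde"` or `"retrograde"`.
#' @return An object of class `tracer_registry`.
#' @examples
#' tracer_registry(c(HRP = "retrograde", "PHA-L" = "anterograde"))
#' @export
tracer_registry <- function(directions) {
  directions <- unlist(directions)
  if (is.null(names(directions)) || any(!nzchar(names(directions))))
    stop("tracer registry entries must be named by chemical", call. = FALSE)
  if (!all(directions %in% c("anterograde", "retrograde")))
    stop("tracer directions must be 'anterograde' or 'retrograde'",
         call. = FALSE)
  structure(as.list(directions), class = "tracer_registry")
}

tracer_direction <- function(registry, chemical) {
  d <- registry[[chemical]]
  if (is.null(d))
    stop(sprintf("tracer chemical '%s' is not registered; add it to the tracer registry", chemical),
         call. = FALSE)
  d
}

#' @export
print.tracer_registry <- function(x, ...) {
  cat("<tracer_registry>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Ordinal connection-strength scale
#'
#' Connection strengths take the ordered values
#' `none < weak < moderate < strong`.  A strength scale carries the mapping
#' from the seven-point labeling-density scale (plus `present-unknown`)
#' onto these strengths.  The mapping is configurable but constrained:
#' it must cover every density category, map `no label` to `none`, and be
#' monotone non-decreasing along the density order.  `present-unknown`
#' sits outside the order and maps to the weakest positive strength by
#' default, so that presence-only reports still count as evidence.
#'
#' @param density_map Named character vector `density label -> strength`.
#' @return An object of class `strength_scale`.
#' @examples
#' default_strength_scale()
#' @export
strength_scale <- function(density_map = NULL) {
  if (is.null(density_map)) density_map <- default_density_map()
  density_map <- unlist(density_map)
  lv <- density_levels()
  missing <- setdiff(lv, names(density_map))
  if (length(missing))
    stop("density map must be total; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(density_map), lv)
  if (length(extra))
    stop("density map names unknown categories: ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (!all(density_map %in% STRENGTH_LEVELS))
    stop("density map values must be strength levels (",
         paste(STRENGTH_LEVELS, collapse = " < "), ")", call. = FALSE)
  if (density_map[["no label"]] != "none")
    stop("'no label' must map to strength 'none'", call. = FALSE)
  ranks <- match(density_map[density_levels(with_unknown = FALSE)],
                 STRENGTH_LEVELS)
  if (any(diff(ranks) < 0))
    stop("density map must be monotone non-decreasing along the density order",
         call. = FALSE)
  if (density_map[["present-unknown"]] == "none")
    stop("'present-unknown' records positive labeling and must map to a positive strength",
         call. = FALSE)
  structure(list(strengths = STRENGTH_LEVELS,
                 density_map = density_map[lv]),
            class = "strength_scale")
}

default_density_map <- function() {
  c("no label" = "none",
    "very sparse label" = "weak",
    "sparse label" = "weak",
    "sparse/moderate label" = "moderate",
    "moderate label" = "moderate",
    "moderate/dense label" = "strong",
    "dense label" = "strong",
    "present-unknown" = "weak")
}

#' @rdname strength_scale
#' @export
default_strength_scale <- function() {
  read_interpretation_config(
    system.file("extdata", "tract-tracing-config.json",
                package = "kefed"))$scale
}

#' @export
print.strength_scale <- function(x, ...) {
  cat("<strength_scale>", paste(x$strengths, collapse = " < "), "\n")
  for (nm in names(x$density_map))
    cat(sprintf("  %-22s -> %s\n", nm, x$density_map[[nm]]))
  invisible(x)
}

strength_rank <- function(s) match(s, STRENGTH_LEVELS)

max_strength <- function(strengths) {
  if (!length(strengths)) return("none")
  STRENGTH_LEVELS[max(strength_rank(strengths))]
}

#' Map a density label to a connection strength
#'
#' @param density_label One of the [density_levels()].
#' @param scale A [strength_scale()].
#' @return A strength level string.
#' @examples
#' density_to_strength("dense label", default_strength_scale())
#' @export
density_to_strength <- function(density_label, scale = default_strength_scale()) {
  stopifnot(inherits(scale, "strength_scale"))
  if (!density_label %in% names(scale$density_map))
    stop(sprintf("unknown density label '%s'", density_label), call. = FALSE)
  unname(scale$density_map[[density_label]])
}

#' Read an interpretation config file
#'
#' A single JSON or YAML file with two maps: `tracers` (chemical name to
#' transport direction) and `density_map` (density label to connection
#' strength).  The package ships a default at
#' `system.file("extdata", "tract-tracing-config.json", package = "kefed")`.
#'
#' @param path File path (`.json`, `.yml`/`.yaml`).
#' @return List with elements `registry` ([tracer_registry()]) and `scale`
#'   ([strength_scale()]).
#' @export
read_interpretation_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$tracers) || is.null(cfg$density_map))
    stop("config must define 'tracers' and 'density_map'", call. = FALSE)
  list(registry = tracer_registry(cfg$tracers),
       scale = strength_scale(cfg$density_map))
}
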