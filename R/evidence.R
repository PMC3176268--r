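#' Column mapping for tract-tracing tables
#'
#' Which node ids of the governing model play the tract-tracing roles the
#' interpreter needs.  Defaults match [reference_model()].
#'
#' @param chemical,injection,labeling,type,density Node ids.
#' @return Named list used by [evidence_for_connection()].
#' @export
tract_tracing_columns <- function(chemical = "injection.chemical",
                                  injection = "injection.location",
                                  labeling = "mapped.location",
                                  type = "labeling.type",
                                  density = "labeling.density") {
  list(chemical = chemical, injection = injection, labeling = labeling,
       type = type, density = density)
}

#' Interpret observations as evidence for a directed projection
#'
#' Applies the two tract-tracing interpretation rules to every row of an
#' observation table and returns the rows that support a projection from
#' `origin` to `termination`:
#'
#' * **anterograde rule** — the tracer moves from cell bodies to axon
#'   terminals, so an anterograde injection whose extent matches the
#'   *origin*, with labeling of type `fibers` or `terminals` whose extent
#'   matches the *termination*, supports origin -> termination;
#' * **retrograde rule** — the tracer moves from axon fibers back to cell
#'   bodies, so a retrograde injection whose extent matches the
#'   *termination*, with `cellular` labeling whose extent matches the
#'   *origin*, supports the same projection.
#'
#' Extent matching uses [resolve_extent()], so evidence may arrive via
#' containment or overlap reasoning; each returned item records the
#' reasoning trails, how direct the match was (`direct`, `via_part`,
#' `via_overlap`), and whether the injection spread over more than one
#' top-level region.  Rows reporting `no label` are negative reports and
#' never yield evidence; `present-unknown` rows yield evidence at the
#' weakest positive strength.
#'
#' @param origin,termination Region abbreviations (projection direction is
#'   origin -> termination).
#' @param table An [observation_table()] of tract-tracing observations.
#' @param atlas A [brain_atlas()].
#' @param registry A [tracer_registry()] covering every chemical in the
#'   table.
#' @param scale A [strength_scale()].
#' @param direct_only Drop evidence whose match needed overlap reasoning.
#' @param columns Node-id mapping, see [tract_tracing_columns()].
#' @return List of `connection_evidence` objects.
#' @examples
#' wx <- worked_example()
#' ev <- evidence_for_connection("CA1", "ENT", wx$table, demo_atlas(),
#'                               wx$registry, default_strength_scale())
#' length(ev)
#' @export
evidence_for_connection <- function(origin, termination, table, atlas,
                                    registry, scale = default_strength_scale(),
                                    direct_only = FALSE,
                                    columns = tract_tracing_columns()) {
  stopifnot(inherits(table, "observation_table"),
            inherits(atlas, "brain_atlas"),
            inherits(registry, "tracer_registry"),
            inherits(scale, "strength_scale"))
  check_region(atlas, origin, termination)
  out <- list()
  for (i in seq_len(nrow(table$rows))) {
    density <- table_value(table, i, columns$density)
    if (density == "no label") next  # negative report
    chem <- table_value(table, i, columns$chemical)
    dir <- tracer_direction(registry, chem)
    type <- table_value(table, i, columns$type)
    inj_ext <- parse_extent(table_value(table, i, columns$injection))
    lab_ext <- parse_extent(table_value(table, i, columns$labeling))

    if (dir == "anterograde") {
      if (!type %in% c("fibers", "terminals")) next
      inj <- resolve_extent(atlas, inj_ext, origin)
      lab <- resolve_extent(atlas, lab_ext, termination)
    } else {
      if (type != "cellular") next
      inj <- resolve_extent(atlas, inj_ext, termination)
      lab <- resolve_extent(atlas, lab_ext, origin)
    }
    if (!inj$result || !lab$result) next

    directness <- trails_directness(inj$trail, lab$trail)
    if (direct_only && directness == "via_overlap") next
    out[[length(out) + 1L]] <- structure(list(
      origin = origin,
      termination = termination,
      strength = density_to_strength(density, scale),
      direction_used = dir,
      directness = directness,
      injection_spread = extent_spreads(atlas, inj_ext),
      row_ref = list(experiment_id = table$rows$experiment_id[i], row = i),
      publication = table$rows$publication[i],
      trails = list(injection = inj$trail, labeling = lab$trail)),
      class = "connection_evidence")
  }
  out
}

trails_directness <- function(inj_trail, lab_trail) {
  v <- c(inj_trail$verdict, lab_trail$verdict)
  if (any(v %in% c("overlap", "overlap_of_part"))) "via_overlap"
  else if (any(v == "contained")) "via_part"
  else "direct"
}

# A deposit spreads when its named regions fall under more than one
# top-level region, or when it only overlaps a region (by definition it
# then extends beyond it).
extent_spreads <- function(atlas, extent) {
  extent <- parse_extent(extent)
  if (any(extent$assertions$relation == "overlaps")) return(TRUE)
  roots <- unique(unlist(lapply(extent$assertions$region,
                                function(r) region_roots(atlas, r))))
  length(roots) > 1L
}

#' @export
print.connection_evidence <- function(x, ...) {
  cat(sprintf("<evidence> %s -> %s: %s (%s, %s%s) [%s / %s row %d]\n",
              x$origin, x$termination, x$strength, x$direction_used,
              x$directness, if (x$injection_spread) ", spread" else "",
              x$publication, x$row_ref$experiment_id, x$row_ref$row))
  invisible(x)
}

#' Tabulate evidence with its provenance
#'
#' One row per evidence item, sorted by publication, experiment and row
#' index, with the reasoning-trail summaries — the drill-down view behind
#' a connection-matrix cell.
#'
#' @param evidence List of `connection_evidence` (from
#'   [evidence_for_connection()]).
#' @return Data frame with columns `publication`, `experiment_id`, `row`,
#'   `origin`, `termination`, `strength`, `direction`, `directness`,
#'   `injection_spread`, `injection_trail`, `labeling_trail`.
#' @export
evidence_report <- function(evidence) {
  cols <- c("publication", "experiment_id", "row", "origin", "termination",
            "strength", "direction", "directness", "injection_spread",
            "injection_trail", "labeling_trail")
  if (!length(evidence)) {
    df <- as.data.frame(stats::setNames(
      rep(list(character()), length(cols)), cols),
      stringsAsFactors = FALSE)
    df$row <- integer()
    df$injection_spread <- logical()
    return(df)
  }
  df <- do.call(rbind, lapply(evidence, function(e)
    data.frame(publication = e$publication,
               experiment_id = e$row_ref$experiment_id,
               row = e$row_ref$row,
               origin = e$origin, termination = e$termination,
               strength = e$strength, direction = e$direction_used,
               directness = e$directness,
               injection_spread = e$injection_spread,
               injection_trail = trail_summary(e$trails$injection),
               labeling_trail = trail_summary(e$trails$labeling),
               stringsAsFactors = FALSE)))
  df <- df[order(df$publication, df$experiment_id, df$row), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build a connection matrix
#'
#' Fills every ordered pair of distinct query regions with the strongest
#' connection strength for which some experimental evidence exists, plus
#' the evidence count.  Cells with no evidence hold `none`/0.  The full
#' evidence lists are kept for drill-down via [matrix_evidence()].
#'
#' @param regions Character vector of region abbreviations (matrix rows =
#'   origins, columns = terminations).
#' @inheritParams evidence_for_connection
#' @return An object of class `connection_matrix` with components
#'   `regions`, `strength` (character matrix), `count` (integer matrix) and
#'   `evidence` (named list of evidence lists).
#' @examples
#' wx <- worked_example()
#' m <- build_matrix(c("CA1", "ENT"), wx$table, demo_atlas(), wx$registry)
#' m
#' @export
build_matrix <- function(regions, table, atlas, registry,
                         scale = default_strength_scale(),
                         direct_only = FALSE,
                         columns = tract_tracing_columns()) {
  check_region(atlas, regions)
  n <- length(regions)
  strength <- matrix("none", n, n, dimnames = list(regions, regions))
  count <- matrix(0L, n, n, dimnames = list(regions, regions))
  evidence <- list()
  for (o in regions) for (t in regions) {
    if (o == t) next
    ev <- evidence_for_connection(o, t, table, atlas, registry, scale,
                                  direct_only = direct_only,
                                  columns = columns)
    if (length(ev)) {
      strength[o, t] <- max_strength(vapply(ev, `[[`, character(1),
                                            "strength"))
      count[o, t] <- length(ev)
      evidence[[paste(o, t, sep = "->")]] <- ev
    }
  }
  structure(list(regions = regions, strength = strength, count = count,
                 evidence = evidence),
            class = "connection_matrix")
}

#' @rdname build_matrix
#' @param matrix A `connection_matrix`.
#' @param origin,termination Region abbreviations of the cell to drill
#'   into.
#' @export
matrix_evidence <- function(matrix, origin, termination) {
  matrix$evidence[[paste(origin, termination, sep = "->")]] %||% list()
}

#' @export
print.connection_matrix <- function(x, ...) {
  cat(sprintf("<connection_matrix> %d x %d regions, %d cells with evidence\n",
              length(x$regions), length(x$regions), length(x$evidence)))
  disp <- matrix(sprintf("%s:%d", x$strength, x$count),
                 nrow = length(x$regions),
                 dimnames = dimnames(x$strength))
  diag(disp) <- "-"
  print(disp, quote = FALSE)
  invisible(x)
}

#' Write a connection matrix as CSV
#'
#' First column holds the origin abbreviations, the header row the
#' termination abbreviations; each cell is `strength:count`.
#'
#' @param matrix A `connection_matrix`.
#' @param path Output path.
#' @export
write_matrix_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "connection_matrix"))
  disp <- matrix(sprintf("%s:%d", matrix$strength, matrix$count),
                 nrow = length(matrix$regions),
                 dimnames = dimnames(matrix$strength))
  diag(disp) <- ""
  df <- data.frame(origin = rownames(disp), disp, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
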