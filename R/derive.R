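#' Derive the parameter context of a measurement
#'
#' A measurement is indexed by every parameter and constant attached to an
#' activity lying on some directed flow path from a start node of the
#' protocol to the activity that produces the measurement.  Where the
#' workflow branches, the context is the union over all such paths.  The
#' returned ordering is deterministic: activities in topological order of
#' the flow graph, variables within an activity sorted by node id.
#'
#' @param model A valid [kefed_model()].
#' @param measurement_id Id of a measurement node.
#' @return An object of class `measurement_context`: list with
#'   `measurement_id` and `context_ids` (character vector of parameter and
#'   constant node ids).
#' @examples
#' ctx <- derive_context(reference_model(), "labeling.density")
#' ctx$context_ids
#' @export
derive_context <- function(model, measurement_id) {
  stopifnot(inherits(model, "kefed_model"))
  n <- model$nodes[[measurement_id]]
  if (is.null(n))
    stop(sprintf("unknown node id '%s'", measurement_id), call. = FALSE)
  if (n$kind != "measurement")
    stop(sprintf("node '%s' is a %s, not a measurement",
                 measurement_id, n$kind), call. = FALSE)
  mo <- edges_of(model, "measurement_of")
  act <- mo$source[mo$target == measurement_id]
  if (length(act) != 1L)
    stop(sprintf("measurement '%s' attaches to %d activities",
                 measurement_id, length(act)), call. = FALSE)

  g <- flow_graph(model)
  # In a finite DAG every ancestor of the activity traces back to a source,
  # so {ancestors} + {activity} is exactly the set of nodes on start->activity
  # flow paths.
  on_path <- if (act %in% igraph::V(g)$name) {
    names(igraph::subcomponent(g, act, mode = "in"))
  } else act
  acts <- intersect(flow_topo_order(model), on_path)
  acts <- acts[vapply(acts, function(a) node_kind(model, a) == "activity",
                      logical(1))]
  if (!act %in% acts) acts <- c(acts, act)

  po <- edges_of(model, "parameter_of")
  ctx <- character()
  for (a in acts) {
    ctx <- c(ctx, sort(po$source[po$target == a]))
  }
  ctx <- ctx[!duplicated(ctx)]
  structure(list(measurement_id = measurement_id, context_ids = ctx),
            class = "measurement_context")
}

# Deterministic topological order of the flow subgraph: Kahn's algorithm
# with a lexicographic tie-break on node id.
flow_topo_order <- function(model) {
  fl <- edges_of(model, "flow")
  kinds <- vapply(model$nodes, function(n) n$kind, character(1))
  nodes <- sort(union(names(model$nodes)[kinds %in% FLOW_KINDS],
                      unique(c(fl$source, fl$target))))
  indeg <- stats::setNames(tabulate(match(fl$target, nodes), length(nodes)),
                           nodes)
  avail <- nodes[indeg == 0]
  out <- character()
  while (length(avail)) {
    avail <- sort(avail)
    n <- avail[1L]; avail <- avail[-1L]
    out <- c(out, n)
    for (m in fl$target[fl$source == n]) {
      indeg[m] <- indeg[m] - 1L
      if (indeg[m] == 0L) avail <- c(avail, m)
    }
  }
  if (length(out) != length(nodes))
    stop("flow graph contains a cycle; validate the model first",
         call. = FALSE)
  out
}

#' @export
print.measurement_context <- function(x, ...) {
  cat(sprintf("context(%s): {%s}\n", x$measurement_id,
              paste(x$context_ids, collapse = ", ")))
  invisible(x)
}

#' Derive the data-entry form of a model
#'
#' Generates the column schema of the spreadsheet that records observations
#' for a model: the union of the measurement contexts of every measurement
#' (each variable once, in context order) followed by the measurements
#' themselves.  Constants are flagged as fixed per experiment.  A model with
#' no measurements derives an empty form.
#'
#' @param model A [kefed_model()]; must validate cleanly.
#' @return An object of class `form_spec`: list with `model_id` and
#'   `columns`, a data frame with columns `node_id`, `label`, `role`
#'   (`constant`/`parameter`/`measurement`) and `fixed`.
#' @examples
#' derive_form(reference_model())
#' @export
derive_form <- function(model) {
  rep <- validate_model(model)
  if (nrow(rep) > 0)
    stop("model is invalid (", nrow(rep), " violations); see validate_model()",
         call. = FALSE)
  kinds <- vapply(model$nodes, function(n) n$kind, character(1))
  meas <- names(kinds)[kinds == "measurement"]
  # order measurements by their activity's topological position, ties by id
  if (length(meas)) {
    mo <- edges_of(model, "measurement_of")
    topo <- flow_topo_order(model)
    pos <- vapply(meas, function(m) match(mo$source[mo$target == m], topo),
                  numeric(1))
    meas <- meas[order(pos, meas)]
  }
  ctx <- character()
  for (m in meas) {
    cm <- derive_context(model, m)$context_ids
    ctx <- c(ctx, cm)
  }
  ctx <- ctx[!duplicated(ctx)]
  ids <- c(ctx, meas)
  cols <- data.frame(
    node_id = ids,
    label = vapply(ids, function(i) model$nodes[[i]]$label, character(1)),
    role = vapply(ids, function(i) node_kind(model, i), character(1)),
    stringsAsFactors = FALSE)
  cols$role[cols$role == "constant"] <- "constant"
  cols$fixed <- cols$role == "constant"
  rownames(cols) <- NULL
  structure(list(model_id = model$id, columns = cols), class = "form_spec")
}

#' @export
print.form_spec <- function(x, ...) {
  cat(sprintf("<form_spec for model '%s'> %d columns\n", x$model_id,
              nrow(x$columns)))
  for (i in seq_len(nrow(x$columns)))
    cat(sprintf("  %-24s %s%s\n", x$columns$node_id[i], x$columns$role[i],
                if (x$columns$fixed[i]) " (fixed per experiment)" else ""))
  invisible(x)
}

form_domain <- function(model, node_id) model$nodes[[node_id]]$domain
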