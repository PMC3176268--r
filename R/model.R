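NODE_KINDS <- c("activity", "material", "parameter", "constant",
                "measurement", "branch", "fork")
VARIABLE_KINDS <- c("parameter", "constant", "measurement")
FLOW_KINDS <- c("material", "activity", "branch", "fork")
EDGE_KINDS <- c("flow", "parameter_of", "measurement_of")

#' Create a node of an experimental-design model
#'
#' Nodes are either workflow elements (`activity`, `material`, `branch`,
#' `fork`) or variables (`parameter`, `constant`, `measurement`).  Variables
#' carry a [value_domain()]; workflow elements do not.
#'
#' @param id Unique, non-empty identifier string.
#' @param kind Node kind; one of `r paste(NODE_KINDS, collapse = ", ")`.
#' @param label Human-readable label (defaults to `id`).
#' @param ontology_term Optional ontology annotation as a compact CURIE
#'   string, e.g. `"obi:OBI_0000426"`.
#' @param domain A [value_domain()] for variable nodes, `NULL` otherwise.
#' @return An object of class `kefed_node`.
#' @export
kefed_node <- function(id, kind, label = id, ontology_term = NULL,
                       domain = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(kind), length(kind) == 1L)
  structure(list(id = id, kind = kind, label = label,
                 ontology_term = ontology_term, domain = domain),
            class = "kefed_node")
}

#' Create an experimental-design (KEfED) model
#'
#' A model is a directed acyclic workflow graph.  `flow` edges connect
#' materials, activities and control-flow nodes (branch/fork) and describe
#' the protocol; `parameter_of` edges attach parameters and constants to the
#' activities they condition; `measurement_of` edges attach each measurement
#' to the single activity that produces it.  Nodes and edges are stored in a
#' canonical sort order so that two structurally equal models compare equal
#' regardless of input order.
#'
#' @param id,name,description Model identity strings.
#' @param nodes List of [kefed_node()] objects.
#' @param edges Data frame with columns `source`, `target`, `kind`.
#' @return An object of class `kefed_model`.
#' @seealso [validate_model()], [derive_context()], [derive_form()],
#'   [read_kefed_model()]
#' @export
kefed_model <- function(id, name = id, description = "", nodes = list(),
                        edges = data.frame(source = character(),
                                           target = character(),
                                           kind = character())) {
  stopifnot(is.list(nodes), is.data.frame(edges))
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      kind = as.character(edges$kind),
                      stringsAsFactors = FALSE)
  ids <- vapply(nodes, function(n) n$id, character(1))
  nodes <- nodes[order(ids)]
  names(nodes) <- sort(ids)
  edges <- unique(edges)
  edges <- edges[order(edges$source, edges$target, edges$kind), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(id = id, name = name, description = description,
                 nodes = nodes, edges = edges),
            class = "kefed_model")
}

#' Convenience edge constructor
#' @param source,target Node ids.
#' @param kind Edge kind: `"flow"`, `"parameter_of"` or `"measurement_of"`.
#' @return One-row data frame.
#' @export
kefed_edge <- function(source, target, kind = "flow") {
  data.frame(source = source, target = target, kind = kind,
             stringsAsFactors = FALSE)
}

node_kind <- function(model, id) {
  n <- model$nodes[[id]]
  if (is.null(n)) NA_character_ else n$kind
}

edges_of <- function(model, kind) {
  model$edges[model$edges$kind == kind, , drop = FALSE]
}

# igraph over the flow subgraph only; isolated flow nodes retained.
flow_graph <- function(model) {
  fl <- edges_of(model, "flow")
  kinds <- vapply(model$nodes, function(n) n$kind, character(1))
  verts <- names(model$nodes)[kinds %in% FLOW_KINDS]
  verts <- union(verts, unique(c(fl$source, fl$target)))
  igraph::graph_from_data_frame(fl[, c("source", "target")],
                                directed = TRUE,
                                vertices = data.frame(name = sort(verts)))
}

curie_ok <- function(x) {
  grepl("^[A-Za-z_][A-Za-z0-9_.-]*:[^[:space:]]+$", x)
}

violation <- function(check, ids, message) {
  data.frame(check = check, ids = paste(ids, collapse = ","),
             message = message, stringsAsFactors = FALSE)
}

empty_report <- function() {
  structure(data.frame(check = character(), ids = character(),
                       message = character(), stringsAsFactors = FALSE),
            class = c("kefed_validation", "data.frame"))
}

#' Validate an experimental-design model
#'
#' Checks every structural invariant of the workflow representation and
#' returns the violations as data, one row per problem: unique node ids,
#' legal node and edge kinds, domains present exactly on variable nodes,
#' well-formed ontology CURIEs, edge endpoints resolving to declared nodes,
#' edge typing rules (flow edges between workflow nodes with no direct
#' material-to-material hand-off; `parameter_of` from parameter/constant to
#' activity; `measurement_of` from activity to measurement), acyclicity of
#' the flow graph with at least one start node, each measurement attached to
#' exactly one activity and each parameter/constant to at least one.
#'
#' @param model A [kefed_model()].
#' @return A `kefed_validation` data frame with columns `check`, `ids`,
#'   `message`; zero rows means the model is valid.
#' @examples
#' m <- reference_model()
#' nrow(validate_model(m))  # 0
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "kefed_model"))
  v <- list()
  add <- function(x) v[[length(v) + 1L]] <<- x

  ids <- vapply(model$nodes, function(n) n$id, character(1))
  if (any(!nzchar(ids)))
    add(violation("node-id", ids[!nzchar(ids)], "empty node id"))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    add(violation("node-id", dup, "duplicate node id"))

  for (n in model$nodes) {
    if (!n$kind %in% NODE_KINDS)
      add(violation("node-kind", n$id,
                    sprintf("unknown node kind '%s'", n$kind)))
    is_var <- n$kind %in% VARIABLE_KINDS
    if (is_var && is.null(n$domain))
      add(violation("domain", n$id,
                    sprintf("%s node lacks a value domain", n$kind)))
    if (!is_var && !is.null(n$domain))
      add(violation("domain", n$id,
                    sprintf("%s node must not carry a value domain", n$kind)))
    if (!is.null(n$domain)) {
      for (p in domain_problems(n$domain))
        add(violation("domain", n$id, p))
    }
    if (!is.null(n$ontology_term) && !curie_ok(n$ontology_term))
      add(violation("ontology-term", n$id,
                    sprintf("'%s' is not a prefix:identifier CURIE",
                            n$ontology_term)))
  }

  e <- model$edges
  bad_kind <- !e$kind %in% EDGE_KINDS
  for (i in which(bad_kind))
    add(violation("edge-kind", c(e$source[i], e$target[i]),
                  sprintf("unknown edge kind '%s'", e$kind[i])))
  known <- names(model$nodes)
  dangling <- !(e$source %in% known) | !(e$target %in% known)
  for (i in which(dangling))
    add(violation("edge-endpoint", c(e$source[i], e$target[i]),
                  "edge endpoint is not a declared node"))

  e <- e[!bad_kind & !dangling, , drop = FALSE]
  for (i in seq_len(nrow(e))) {
    sk <- node_kind(model, e$source[i])
    tk <- node_kind(model, e$target[i])
    pair <- c(e$source[i], e$target[i])
    switch(e$kind[i],
      flow = {
        if (!sk %in% FLOW_KINDS || !tk %in% FLOW_KINDS)
          add(violation("flow-edge", pair,
                        "flow edges connect material/activity/branch/fork nodes only"))
        else if (sk == "material" && tk == "material")
          add(violation("flow-edge", pair,
                        "materials must be transformed by an activity, not flow into another material"))
      },
      parameter_of = {
        if (!sk %in% c("parameter", "constant") || tk != "activity")
          add(violation("parameter-of", pair,
                        "parameter_of edges run parameter/constant -> activity"))
      },
      measurement_of = {
        if (sk != "activity" || tk != "measurement")
          add(violation("measurement-of", pair,
                        "measurement_of edges run activity -> measurement"))
      })
  }

  fl <- e[e$kind == "flow", , drop = FALSE]
  if (nrow(fl)) {
    g <- igraph::graph_from_data_frame(fl[, c("source", "target")])
    if (!igraph::is_dag(g)) {
      cyc <- cycle_members(fl$source, fl$target)
      add(violation("flow-acyclic", cyc, "flow graph contains a cycle"))
    } else if (!any(igraph::degree(g, mode = "in") == 0))
      add(violation("flow-start", character(),
                    "flow graph has no start node"))
  }

  kinds <- vapply(model$nodes, function(n) n$kind, character(1))
  mo <- e[e$kind == "measurement_of", , drop = FALSE]
  for (m in names(kinds)[kinds == "measurement"]) {
    k <- sum(mo$target == m)
    if (k != 1L)
      add(violation("measurement-attachment", m,
                    sprintf("measurement attaches to %d activities (need exactly 1)", k)))
  }
  po <- e[e$kind == "parameter_of", , drop = FALSE]
  for (p in names(kinds)[kinds %in% c("parameter", "constant")]) {
    if (!p %in% po$source)
      add(violation("parameter-attachment", p,
                    "parameter/constant attaches to no activity"))
  }

  rep <- if (length(v)) do.call(rbind, v) else empty_report()
  structure(rep, class = c("kefed_validation", "data.frame"))
}

# Kahn's algorithm; the nodes left unsorted are exactly those on/blocked by
# cycles, which is what the error message should name.
cycle_members <- function(src, dst) {
  nodes <- sort(unique(c(src, dst)))
  indeg <- stats::setNames(tabulate(match(dst, nodes), length(nodes)), nodes)
  queue <- nodes[indeg == 0]
  while (length(queue)) {
    n <- queue[1L]; queue <- queue[-1L]
    for (out in dst[src == n]) {
      indeg[out] <- indeg[out] - 1L
      if (indeg[out] == 0L) queue <- c(queue, out)
    }
  }
  names(indeg)[indeg > 0]
}

#' @export
print.kefed_validation <- function(x, ...) {
  if (nrow(x) == 0) cat("model/table valid: no violations\n")
  else {
    cat(nrow(x), "violation(s):\n")
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s (%s)\n", x$check[i], x$message[i], x$ids[i]))
  }
  invisible(x)
}

#' @export
print.kefed_model <- function(x, ...) {
  kinds <- vapply(x$nodes, function(n) n$kind, character(1))
  cat(sprintf("<kefed_model '%s'> %d nodes (%s), %d edges\n",
              x$id, length(x$nodes),
              paste(sprintf("%d %s", as.integer(table(kinds)),
                            names(table(kinds))), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}
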