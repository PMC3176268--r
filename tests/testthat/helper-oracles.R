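# Independent oracles used by the property tests.  These deliberately take
# the slow, literal route (exhaustive path enumeration, boolean matrix
# closure, direct evaluation of the four-condition definition) so they share
# no code with the package's reasoning paths.

# All flow paths from every start node to `to`, as lists of node ids.
enumerate_flow_paths <- function(model, to) {
  fl <- model$edges[model$edges$kind == "flow", , drop = FALSE]
  nodes <- unique(c(fl$source, fl$target))
  starts <- setdiff(nodes, fl$target)
  paths <- list()
  walk <- function(at, acc) {
    if (at == to) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    for (nxt in fl$target[fl$source == at]) walk(nxt, c(acc, nxt))
  }
  for (s in starts) walk(s, s)
  paths
}

# Context by brute force: union of parameters/constants attached to
# activities on any start -> activity path (as an unordered set).
oracle_context <- function(model, measurement_id) {
  mo <- model$edges[model$edges$kind == "measurement_of", , drop = FALSE]
  act <- mo$source[mo$target == measurement_id]
  po <- model$edges[model$edges$kind == "parameter_of", , drop = FALSE]
  paths <- enumerate_flow_paths(model, act)
  if (!length(paths)) paths <- list(act)  # isolated activity
  ctx <- character()
  for (p in paths) ctx <- union(ctx, po$source[po$target %in% p])
  sort(ctx)
}

# Boolean transitive closure of containment via repeated matrix products.
closure_matrix <- function(atlas) {
  regs <- atlas$regions$abbrev
  n <- length(regs)
  adj <- matrix(FALSE, n, n, dimnames = list(regs, regs))
  for (i in seq_len(nrow(atlas$part_of)))
    adj[atlas$part_of$child[i], atlas$part_of$parent[i]] <- TRUE
  clo <- adj
  repeat {
    nxt <- clo | (clo %*% adj > 0)
    if (identical(nxt, clo)) break
    clo <- nxt
  }
  clo
}

overlaps_matrix <- function(atlas) {
  regs <- atlas$regions$abbrev
  ov <- matrix(FALSE, length(regs), length(regs),
               dimnames = list(regs, regs))
  for (i in seq_len(nrow(atlas$overlaps))) {
    ov[atlas$overlaps$a[i], atlas$overlaps$b[i]] <- TRUE
    ov[atlas$overlaps$b[i], atlas$overlaps$a[i]] <- TRUE
  }
  ov
}

# Literal evaluation of the four conditions of the combined
# containment-or-overlap relation.
oracle_part_of_or_overlaps <- function(atlas, sub, super) {
  clo <- closure_matrix(atlas)
  ov <- overlaps_matrix(atlas)
  regs <- atlas$regions$abbrev
  sub == super ||
    clo[sub, super] ||
    ov[sub, super] ||
    any(vapply(regs, function(r) clo[r, super] && ov[sub, r], logical(1)))
}

# Mirror a simulated corpus table: swap tracer direction, swap the
# injection and labeling extents, and flip the labeling type between its
# anterograde and retrograde readings.
mirror_corpus_table <- function(table) {
  rows <- table$rows
  rows$injection.chemical <- ifelse(rows$injection.chemical == "tracer-A",
                                    "tracer-R", "tracer-A")
  tmp <- rows$injection.location
  rows$injection.location <- rows$mapped.location
  rows$mapped.location <- tmp
  rows$labeling.type <- ifelse(rows$labeling.type == "terminals",
                               "cellular", "terminals")
  observation_table(table$model_id, rows)
}

# Ground truth as a strength matrix over the corpus query regions.
truth_matrix <- function(corpus) {
  regs <- corpus$regions
  m <- matrix("none", length(regs), length(regs),
              dimnames = list(regs, regs))
  gt <- corpus$ground_truth
  for (i in seq_len(nrow(gt)))
    m[gt$origin[i], gt$termination[i]] <- gt$strength[i]
  m
}

expect_clean <- function(report) expect_equal(nrow(report), 0L)
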