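#' Read and write model documents
#'
#' Models are stored as JSON documents with top-level keys `id`, `name`,
#' `description`, `nodes` and `edges`.  The document schema is shipped with
#' the package (`system.file("schema", "kefed-model.schema.json",
#' package = "kefed")`).  Reading is canonicalizing: node and edge order on
#' disk does not affect the resulting object, so `read_kefed_model(path)`
#' after `write_kefed_model(model, path)` is structurally identical to
#' `model`.
#'
#' @param path File path.
#' @param model A [kefed_model()]; writing requires it to validate cleanly.
#' @return `read_kefed_model()` returns a `kefed_model`;
#'   `write_kefed_model()` returns `path` invisibly.
#' @export
read_kefed_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("cannot parse model document: ",
                         conditionMessage(e), call. = FALSE))
  model_from_document(doc)
}

model_from_document <- function(doc) {
  need <- function(x, key, ptr) {
    if (is.null(x[[key]]))
      stop(sprintf("model document invalid at %s/%s: missing key", ptr, key),
           call. = FALSE)
    x[[key]]
  }
  for (key in c("id", "name", "description", "nodes", "edges"))
    need(doc, key, "")
  nodes <- lapply(seq_along(doc$nodes), function(i) {
    nd <- doc$nodes[[i]]
    ptr <- sprintf("/nodes/%d", i - 1L)
    id <- need(nd, "id", ptr)
    kind <- need(nd, "kind", ptr)
    dom <- NULL
    if (!is.null(nd$domain)) {
      dk <- need(nd$domain, "kind", paste0(ptr, "/domain"))
      dom <- value_domain(dk,
                          levels = unlist(nd$domain$levels),
                          units = nd$domain$units)
    }
    kefed_node(id, kind,
               label = if (is.null(nd$label)) id else nd$label,
               ontology_term = nd$ontology_term,
               domain = dom)
  })
  edges <- if (length(doc$edges)) {
    do.call(rbind, lapply(seq_along(doc$edges), function(i) {
      ed <- doc$edges[[i]]
      ptr <- sprintf("/edges/%d", i - 1L)
      data.frame(source = need(ed, "source", ptr),
                 target = need(ed, "target", ptr),
                 kind = need(ed, "kind", ptr),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(source = character(), target = character(),
               kind = character())
  }
  kefed_model(doc$id, doc$name, doc$description, nodes, edges)
}

#' @rdname read_kefed_model
#' @export
write_kefed_model <- function(model, path) {
  rep <- validate_model(model)
  if (nrow(rep) > 0)
    stop("refusing to write an invalid model (", nrow(rep), " violations)",
         call. = FALSE)
  doc <- model_to_document(model)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

model_to_document <- function(model) {
  nodes <- lapply(unname(model$nodes), function(n) {
    out <- list(id = n$id, kind = n$kind, label = n$label)
    if (!is.null(n$ontology_term)) out$ontology_term <- n$ontology_term
    if (!is.null(n$domain)) {
      d <- list(kind = n$domain$kind)
      if (!is.null(n$domain$levels)) d$levels <- as.list(n$domain$levels)
      if (!is.null(n$domain$units)) d$units <- n$domain$units
      out$domain <- d
    }
    out
  })
  edges <- lapply(seq_len(nrow(model$edges)), function(i)
    list(source = model$edges$source[i], target = model$edges$target[i],
         kind = model$edges$kind[i]))
  list(id = model$id, name = model$name, description = model$description,
       nodes = nodes, edges = edges)
}
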