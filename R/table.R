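#' Observation tables
#'
#' An observation table stores the data points curated for one
#' experimental-design model.  One row is one data point — for
#' tract-tracing, one labeling report for one injection — carrying its
#' experiment id and publication key as provenance plus one value per
#' derived form column, keyed by node id.  Region-extent values are stored
#' in their flat expression form (see [parse_extent()]).
#'
#' @param model_id Id of the model the rows conform to.
#' @param rows Data frame with columns `experiment_id`, `publication` and
#'   one column per form column (named by node id).  Cells holding
#'   [region_extent()] objects are serialized to expression strings.
#' @return An object of class `observation_table`.
#' @seealso [validate_table()], [read_table()], [derive_form()]
#' @export
observation_table <- function(model_id, rows) {
  stopifnot(is.character(model_id), length(model_id) == 1L,
            is.data.frame(rows))
  if (!all(c("experiment_id", "publication") %in% names(rows)))
    stop("rows need 'experiment_id' and 'publication' columns",
         call. = FALSE)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  for (cn in names(rows)) {
    if (is.list(rows[[cn]])) {
      rows[[cn]] <- vapply(rows[[cn]], function(v) {
        if (inherits(v, "region_extent")) format_extent(v)
        else as.character(v)
      }, character(1))
    } else if (is.factor(rows[[cn]])) {
      rows[[cn]] <- as.character(rows[[cn]])
    }
  }
  data_cols <- setdiff(names(rows), c("experiment_id", "publication"))
  rows <- rows[, c("experiment_id", "publication", sort(data_cols)),
               drop = FALSE]
  rownames(rows) <- NULL
  structure(list(model_id = model_id, rows = rows),
            class = "observation_table")
}

#' @export
print.observation_table <- function(x, ...) {
  cat(sprintf("<observation_table for model '%s'> %d rows, %d experiments, %d publications\n",
              x$model_id, nrow(x$rows),
              length(unique(x$rows$experiment_id)),
              length(unique(x$rows$publication))))
  invisible(x)
}

table_value <- function(table, i, node_id) table$rows[[node_id]][i]

#' Validate an observation table against its model
#'
#' Reports, as data with row indices: missing or extra columns relative to
#' the model's derived form; values outside their column's domain; and,
#' within each experiment, constant-role columns that take more than one
#' value (a constant is fixed per experiment).
#'
#' @param table An [observation_table()].
#' @param model The [kefed_model()] the table claims to conform to; a model
#'   id mismatch is an error.
#' @return A `kefed_validation` data frame; zero rows means valid.
#' @export
validate_table <- function(table, model) {
  stopifnot(inherits(table, "observation_table"),
            inherits(model, "kefed_model"))
  if (table$model_id != model$id)
    stop(sprintf("table references model '%s' but was checked against '%s'",
                 table$model_id, model$id), call. = FALSE)
  form <- derive_form(model)
  v <- list()
  add <- function(x) v[[length(v) + 1L]] <<- x

  have <- setdiff(names(table$rows), c("experiment_id", "publication"))
  for (m in setdiff(form$columns$node_id, have))
    add(violation("column", m, "form column missing from table"))
  for (m in setdiff(have, form$columns$node_id))
    add(violation("column", m, "table column not in derived form"))

  present <- intersect(form$columns$node_id, have)
  for (cn in present) {
    dom <- form_domain(model, cn)
    for (i in seq_len(nrow(table$rows))) {
      val <- table_value(table, i, cn)
      chk <- domain_check(dom, val)
      if (!isTRUE(chk))
        add(violation("domain", cn, sprintf("row %d: %s", i, chk)))
    }
  }

  const_cols <- intersect(
    form$columns$node_id[form$columns$role == "constant"], present)
  for (cn in const_cols) {
    for (ex in unique(table$rows$experiment_id)) {
      vals <- unique(table$rows[[cn]][table$rows$experiment_id == ex])
      if (length(vals) > 1L)
        add(violation("constant", cn,
                      sprintf("experiment '%s': constant takes %d values (%s)",
                              ex, length(vals),
                              paste(vals, collapse = " / "))))
    }
  }
  rep <- if (length(v)) do.call(rbind, v) else empty_report()
  structure(rep, class = c("kefed_validation", "data.frame"))
}

#' Read and write observation tables
#'
#' CSV files (RFC 4180, UTF-8, header row) use the node *labels* of the
#' model's form as column headers, preceded by `experiment_id` and
#' `publication`; JSON-lines files hold one object per row keyed by node
#' *id*.  Region extents travel as flat expressions such as
#' `part_of(ENTl)|overlaps(PRC)`.  Both formats round-trip:
#' `read_table(write_table(t, ...), model)` equals `t`.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param model The governing [kefed_model()] (needed to map labels to node
#'   ids and to type the columns).
#' @param table An [observation_table()].
#' @param format `"csv"` or `"json"`.
#' @return `read_table()` returns an [observation_table()];
#'   `write_table()` returns `path` invisibly.
#' @export
read_table <- function(path, model, format = NULL) {
  format <- format %||% guess_format(path)
  form <- derive_form(model)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                          encoding = "UTF-8")
    lab2id <- stats::setNames(form$columns$node_id, form$columns$label)
    out <- data.frame(row.names = seq_len(nrow(df)))
    for (cn in names(df)) {
      if (cn %in% c("experiment_id", "publication")) out[[cn]] <- df[[cn]]
      else if (cn %in% names(lab2id)) out[[lab2id[[cn]]]] <- df[[cn]]
      else stop(sprintf("unknown column '%s' (not in the derived form)", cn),
                call. = FALSE)
    }
    df <- out
  } else if (format == "json") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) jsonlite::fromJSON(l,
                                                         simplifyVector = TRUE))
    keys <- unique(unlist(lapply(rows, names)))
    bad <- setdiff(keys, c("experiment_id", "publication",
                           form$columns$node_id))
    if (length(bad))
      stop("unknown column(s): ", paste(bad, collapse = ", "), call. = FALSE)
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(lapply(r, as.character), stringsAsFactors = FALSE,
                    check.names = FALSE)))
  } else stop("unknown table format: ", format, call. = FALSE)

  # type numeric columns; check extent cells parse, reporting the address
  for (cn in intersect(form$columns$node_id, names(df))) {
    dom <- form_domain(model, cn)
    if (dom$kind == "numeric") {
      df[[cn]] <- as.numeric(df[[cn]])
    } else if (dom$kind == "region_extent") {
      for (i in seq_along(df[[cn]])) {
        parsed <- try(parse_extent(df[[cn]][i]), silent = TRUE)
        if (inherits(parsed, "try-error"))
          stop(sprintf("row %d, column '%s': unparseable extent '%s'",
                       i, cn, df[[cn]][i]), call. = FALSE)
        df[[cn]][i] <- format_extent(parsed)  # canonical token spelling
      }
    }
  }
  observation_table(model$id, df)
}

#' @rdname read_table
#' @export
write_table <- function(table, path, model, format = NULL) {
  stopifnot(inherits(table, "observation_table"))
  format <- format %||% guess_format(path)
  form <- derive_form(model)
  ids <- intersect(form$columns$node_id, names(table$rows))
  if (format == "csv") {
    df <- table$rows[, c("experiment_id", "publication", ids), drop = FALSE]
    id2lab <- stats::setNames(form$columns$label, form$columns$node_id)
    names(df) <- c("experiment_id", "publication", unname(id2lab[ids]))
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else if (format == "json") {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(table$rows))) {
      row <- as.list(table$rows[i, c("experiment_id", "publication", ids),
                                drop = FALSE])
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE), con)
    }
  } else stop("unknown table format: ", format, call. = FALSE)
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         csv = "csv",
         json = , jsonl = , ndjson = "json",
         stop("cannot infer table format from extension '", ext, "'",
              call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
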