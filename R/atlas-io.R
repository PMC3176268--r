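#' Read and write atlas files
#'
#' Two on-disk formats are supported.  The native CSV dialect is a single
#' file with three sections introduced by the header lines `#regions`
#' (rows `abbrev,name,source`), `#part_of` (rows `child,parent`) and
#' `#overlaps` (rows `a,b`); blank lines are ignored and duplicate pairs
#' are deduplicated.  The `bams_xml` format reads a BAMS-style XML region
#' export: `<region>` elements with `abbrev`/`name` attributes (or child
#' elements) and nested `<parent>` elements naming the enclosing region.
#'
#' @param path File path.
#' @param format `"csv"` or `"bams_xml"`.
#' @param atlas A [brain_atlas()] (for writing).
#' @return `load_atlas()` returns a [brain_atlas()]; integrity problems
#'   (containment cycles, undeclared regions in a pair) raise errors naming
#'   the offending regions.
#' @export
load_atlas <- function(path, format = c("csv", "bams_xml")) {
  format <- match.arg(format)
  if (format == "csv") load_atlas_csv(path) else load_atlas_bams_xml(path)
}

load_atlas_csv <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  section <- NA_character_
  regions <- list(); part_of <- list(); overlaps <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      sec <- sub("^#\\s*", "", ln)
      if (!sec %in% c("regions", "part_of", "overlaps"))
        stop(sprintf("line %d: unknown atlas section '#%s'", i, sec),
             call. = FALSE)
      section <- sec
      next
    }
    if (is.na(section))
      stop(sprintf("line %d: data before any #section header", i),
           call. = FALSE)
    f <- strsplit(ln, ",", fixed = TRUE)[[1]]
    f <- trimws(f)
    if (section == "regions") {
      regions[[length(regions) + 1L]] <-
        data.frame(abbrev = f[1],
                   name = if (length(f) >= 2) f[2] else f[1],
                   source = if (length(f) >= 3) f[3] else "",
                   stringsAsFactors = FALSE)
    } else {
      if (length(f) != 2L)
        stop(sprintf("line %d: expected two fields in #%s", i, section),
             call. = FALSE)
      row <- data.frame(x = f[1], y = f[2], stringsAsFactors = FALSE)
      if (section == "part_of") part_of[[length(part_of) + 1L]] <- row
      else overlaps[[length(overlaps) + 1L]] <- row
    }
  }
  bind2 <- function(lst, n1, n2) {
    if (!length(lst))
      return(stats::setNames(data.frame(character(), character(),
                                        stringsAsFactors = FALSE), c(n1, n2)))
    out <- do.call(rbind, lst)
    stats::setNames(out, c(n1, n2))
  }
  brain_atlas(
    regions = if (length(regions)) do.call(rbind, regions)
              else data.frame(abbrev = character(), name = character(),
                              source = character()),
    part_of = bind2(part_of, "child", "parent"),
    overlaps = bind2(overlaps, "a", "b"))
}

load_atlas_bams_xml <- function(path) {
  doc <- xml2::read_xml(path)
  regs <- xml2::xml_find_all(doc, ".//region")
  if (!length(regs))
    stop("no <region> elements found in XML atlas export", call. = FALSE)
  grab <- function(node, what) {
    v <- xml2::xml_attr(node, what)
    if (is.na(v)) {
      ch <- xml2::xml_find_first(node, sprintf("./%s", what))
      v <- if (inherits(ch, "xml_missing")) NA_character_
           else xml2::xml_text(ch)
    }
    v
  }
  abbrev <- vapply(regs, grab, character(1), what = "abbrev")
  nm <- vapply(regs, grab, character(1), what = "name")
  if (anyNA(abbrev))
    stop("a <region> element lacks an abbrev", call. = FALSE)
  nm[is.na(nm)] <- abbrev[is.na(nm)]
  part_of <- do.call(rbind, c(list(
    data.frame(child = character(), parent = character())),
    lapply(seq_along(regs), function(i) {
      parents <- xml2::xml_text(xml2::xml_find_all(regs[[i]], "./parent"))
      if (!length(parents)) return(NULL)
      data.frame(child = abbrev[i], parent = parents,
                 stringsAsFactors = FALSE)
    })))
  src <- xml2::xml_attr(xml2::xml_root(doc), "source")
  if (is.na(src)) src <- ""
  brain_atlas(data.frame(abbrev = abbrev, name = nm, source = src,
                         stringsAsFactors = FALSE),
              part_of = part_of)
}

#' @rdname load_atlas
#' @export
write_atlas_csv <- function(atlas, path) {
  stopifnot(inherits(atlas, "brain_atlas"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#regions", con)
  writeLines(sprintf("%s,%s,%s", atlas$regions$abbrev, atlas$regions$name,
                     atlas$regions$source), con)
  writeLines("#part_of", con)
  if (nrow(atlas$part_of))
    writeLines(sprintf("%s,%s", atlas$part_of$child, atlas$part_of$parent),
               con)
  writeLines("#overlaps", con)
  if (nrow(atlas$overlaps))
    writeLines(sprintf("%s,%s", atlas$overlaps$a, atlas$overlaps$b), con)
  invisible(path)
}
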