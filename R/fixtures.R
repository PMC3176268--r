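# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' The reference tract-tracing experimental-design model
#'
#' The generic tract-tracing protocol as a workflow: an experimental
#' subject receives a tracer microinjection, is perfused, the dissected
#' brain is sectioned, the sections are immunostained and mounted, and the
#' slides are microscopically mapped onto a standard parcellation.  The
#' variables are one constant (taxonomic class, fixed because only rat
#' studies are considered), three parameters (injection chemical, injection
#' location, mapped location — the last two valued as region extents) and
#' two measurements read off the mapping step: labeling type (nominal:
#' cellular, fibers, terminals) and labeling density (the seven-point
#' ordinal scale plus `present-unknown`).
#'
#' @return A valid [kefed_model()].
#' @examples
#' derive_form(reference_model())
#' @export
reference_model <- function() {
  extent_dom <- value_domain("region_extent")
  nodes <- list(
    kefed_node("subject", "material", "experimental subject",
               ontology_term = "obi:OBI_0100026"),
    kefed_node("injection", "activity", "tracer injection",
               ontology_term = "obi:OBI_0000426"),
    kefed_node("perfusion", "activity", "perfusion",
               ontology_term = "obi:OBI_0000919"),
    kefed_node("brain", "material", "dissected brain",
               ontology_term = "fma:FMA_50801"),
    kefed_node("sectioning", "activity", "tissue sectioning",
               ontology_term = "nif:birnlex_2156"),
    kefed_node("sections", "material", "tissue sections",
               ontology_term = "nif:birnlex_2169"),
    kefed_node("immunostaining", "activity", "immunohistochemistry",
               ontology_term = "nif:nlx_inv_20090609"),
    kefed_node("slides", "material", "immunostained slides"),
    kefed_node("mapping", "activity", "neuroanatomical mapping and analysis",
               ontology_term = "obi:OBI_0600020"),
    kefed_node("taxonomic.class", "constant", "taxonomic class",
               domain = value_domain("free_text")),
    kefed_node("injection.chemical", "parameter", "injection chemical",
               domain = value_domain("free_text")),
    kefed_node("injection.location", "parameter", "injection location",
               domain = extent_dom),
    kefed_node("mapped.location", "parameter", "labeling location",
               domain = extent_dom),
    kefed_node("labeling.type", "measurement", "labeling type",
               domain = value_domain("nominal",
                                     levels = c("cellular", "fibers",
                                                "terminals"))),
    kefed_node("labeling.density", "measurement", "labeling density",
               domain = value_domain("ordinal", levels = density_levels())))
  chain <- c("subject", "injection", "perfusion", "brain", "sectioning",
             "sections", "immunostaining", "slides", "mapping")
  edges <- rbind(
    data.frame(source = chain[-length(chain)], target = chain[-1],
               kind = "flow", stringsAsFactors = FALSE),
    kefed_edge("taxonomic.class", "injection", "parameter_of"),
    kefed_edge("injection.chemical", "injection", "parameter_of"),
    kefed_edge("injection.location", "injection", "parameter_of"),
    kefed_edge("mapped.location", "mapping", "parameter_of"),
    kefed_edge("mapping", "labeling.type", "measurement_of"),
    kefed_edge("mapping", "labeling.density", "measurement_of"))
  kefed_model("tract-tracing", "generic tract-tracing experiment",
              paste("Generic anterograde/retrograde tract-tracing protocol:",
                    "injection, perfusion, sectioning, immunostaining,",
                    "neuroanatomical mapping."),
              nodes, edges)
}

#' The hippocampal demo atlas
#'
#' A small parcellation around the hippocampal formation: CA1, the
#' entorhinal area ENT with its lateral and medial parts (ENTl, ENTm), the
#' postsubiculum POST, and the retrosplenial area RSP with dorsal and
#' ventral parts, the ventral part further divided into RSPv-a and
#' RSPv-b/c.  Three additional regions (ENTadj1..3) stand in for the
#' unnamed areas adjacent to ENT that tracer deposits in the worked example
#' spilled into; they are synthetic placeholders, not atlas structures.
#' The base atlas asserts no overlap pairs — overlap enters through the
#' extents recorded in the data.
#'
#' @return A [brain_atlas()].
#' @examples
#' is_part_of(demo_atlas(), "ENTm", "ENT")
#' @export
demo_atlas <- function() {
  regions <- data.frame(
    abbrev = c("CA1", "ENT", "ENTl", "ENTm", "POST",
               "RSP", "RSPd", "RSPv", "RSPv-a", "RSPv-b/c",
               "ENTadj1", "ENTadj2", "ENTadj3"),
    name = c("field CA1", "entorhinal area", "entorhinal area lateral part",
             "entorhinal area medial part", "postsubiculum",
             "retrosplenial area", "retrosplenial area dorsal part",
             "retrosplenial area ventral part",
             "retrosplenial area ventral part zone a",
             "retrosplenial area ventral part zones b/c",
             "synthetic neighbor region 1 adjacent to ENT",
             "synthetic neighbor region 2 adjacent to ENT",
             "synthetic neighbor region 3 adjacent to ENT"),
    source = "demo", stringsAsFactors = FALSE)
  part_of <- data.frame(
    child = c("ENTl", "ENTm", "RSPd", "RSPv", "RSPv-a", "RSPv-b/c"),
    parent = c("ENT", "ENT", "RSP", "RSP", "RSPv", "RSPv"),
    stringsAsFactors = FALSE)
  brain_atlas(regions, part_of)
}

#' The CA1-to-entorhinal worked example
#'
#' Ten curated tract-tracing data points from five publications bearing on
#' the projection from field CA1 to the entorhinal area (ENT): a retrograde
#' study with three injections (one in ENT, two in its subdivisions ENTl
#' and ENTm) all labeling cells in CA1; a retrograde study with three
#' injections whose deposits only overlapped ENT while spilling into
#' adjacent areas, again labeling CA1; two single-injection retrograde
#' experiments (published separately) with ENT injections and CA1 labeling;
#' and an anterograde study with two CA1 injections producing terminal
#' labeling in ENT.  Only the presence of labeling is reported, so every
#' positive density is `present-unknown`.
#'
#' @return List with `table` (an [observation_table()] conforming to
#'   [reference_model()]) and `registry` (a [tracer_registry()] covering
#'   the tracers used).
#' @examples
#' wx <- worked_example()
#' length(unique(wx$table$rows$publication))  # 5
#' @export
worked_example <- function() {
  row <- function(pub, exp, inj, lab, type, chem) {
    data.frame(experiment_id = exp, publication = pub,
               taxonomic.class = "Rattus norvegicus",
               injection.chemical = chem,
               injection.location = inj,
               mapped.location = lab,
               labeling.type = type,
               labeling.density = "present-unknown",
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    row("Beckstead-1976", "beckstead-e1", "coextensive_with(ENT)",
        "coextensive_with(CA1)", "cellular", "HRP"),
    row("Beckstead-1976", "beckstead-e2", "coextensive_with(ENTl)",
        "coextensive_with(CA1)", "cellular", "HRP"),
    row("Beckstead-1976", "beckstead-e3", "coextensive_with(ENTm)",
        "coextensive_with(CA1)", "cellular", "HRP"),
    row("Deacon-1983", "deacon-e1", "overlaps(ENT)|overlaps(ENTadj1)",
        "coextensive_with(CA1)", "cellular", "HRP"),
    row("Deacon-1983", "deacon-e2", "overlaps(ENT)|overlaps(ENTadj2)",
        "coextensive_with(CA1)", "cellular", "HRP"),
    row("Deacon-1983", "deacon-e3", "overlaps(ENT)|overlaps(ENTadj3)",
        "coextensive_with(CA1)", "cellular", "HRP"),
    row("Swanson-1977", "swanson77-e1", "coextensive_with(ENT)",
        "coextensive_with(CA1)", "cellular", "HRP"),
    row("Swanson-1981", "swanson81-e1", "coextensive_with(ENT)",
        "coextensive_with(CA1)", "cellular", "HRP"),
    row("vanGroen-1990", "vangroen-e1", "coextensive_with(CA1)",
        "coextensive_with(ENT)", "terminals", "PHA-L"),
    row("vanGroen-1990", "vangroen-e2", "coextensive_with(CA1)",
        "coextensive_with(ENT)", "terminals", "PHA-L"))
  list(table = observation_table("tract-tracing", rows),
       registry = tracer_registry(c(HRP = "retrograde",
                                    "PHA-L" = "anterograde")))
}

#' Seeded random experimental-design models
#'
#' Generates a random valid workflow model: a layered flow DAG of materials
#' and activities (with occasional branch/fork nodes), random parameters
#' and constants attached to activities, and one or more measurements.
#' Used for property tests of context derivation against exhaustive path
#' enumeration.
#'
#' @param seed Integer seed.
#' @param n_nodes Upper bound on total node count.
#' @return A [kefed_model()].
#' @export
random_kefed_model <- function(seed, n_nodes = 20) {
  with_seed(seed, {
    n_act <- sample(2:5, 1)
    flow_ids <- "m0"
    flow_kinds <- c(m0 = "material")
    edges <- list()
    add_edge <- function(s, t, k = "flow")
      edges[[length(edges) + 1L]] <<- kefed_edge(s, t, k)
    for (i in seq_len(n_act)) {
      a <- sprintf("act%02d", i)
      # each activity consumes 1-2 earlier flow nodes (never another
      # activity's raw material twice in a row -- material->material is
      # the only forbidden hand-off and activities accept anything)
      n_in <- sample(1:2, 1)
      for (s in sample(flow_ids, min(n_in, length(flow_ids))))
        add_edge(s, a)
      flow_ids <- c(flow_ids, a)
      flow_kinds[a] <- "activity"
      if (stats::runif(1) < 0.4) {  # activity emits a material
        m <- sprintf("mat%02d", i)
        add_edge(a, m)
        flow_ids <- c(flow_ids, m)
        flow_kinds[m] <- "material"
      }
      if (stats::runif(1) < 0.25 && i < n_act) {  # control-flow element
        b <- sprintf("cf%02d", i)
        add_edge(a, b)
        flow_ids <- c(flow_ids, b)
        flow_kinds[b] <- sample(c("branch", "fork"), 1)
      }
    }
    acts <- names(flow_kinds)[flow_kinds == "activity"]
    budget <- n_nodes - length(flow_ids)
    n_var <- max(2L, min(budget - 1L, sample(2:6, 1)))
    nodes <- mapply(function(id, k) kefed_node(id, k),
                    names(flow_kinds), flow_kinds, SIMPLIFY = FALSE)
    for (i in seq_len(n_var - 1L)) {
      vk <- sample(c("parameter", "constant"), 1, prob = c(0.8, 0.2))
      vid <- sprintf("p%02d", i)
      nodes[[vid]] <- kefed_node(vid, vk,
                                 domain = value_domain("free_text"))
      for (a in sample(acts, sample(1:min(2, length(acts)), 1)))
        add_edge(vid, a, "parameter_of")
    }
    n_meas <- sample(1:2, 1)
    for (i in seq_len(n_meas)) {
      mid <- sprintf("meas%02d", i)
      nodes[[mid]] <- kefed_node(mid, "measurement",
                                 domain = value_domain("numeric"))
      add_edge(sample(acts, 1), mid, "measurement_of")
    }
    kefed_model(sprintf("random-%d", seed), nodes = unname(nodes),
                edges = do.call(rbind, edges))
  })
}

#' Seeded random atlases
#'
#' Generates a random region hierarchy (each region may declare up to two
#' parents among earlier regions, so containment is a DAG, not only a
#' tree) and random overlap pairs.  Used for property tests of the
#' spatial-reasoning operations against brute-force evaluation.
#'
#' @param seed Integer seed.
#' @param n_regions Number of regions (<= a few dozen keeps brute force
#'   cheap).
#' @param p_part Probability that a region declares each potential parent.
#' @param p_overlap Expected fraction of region pairs asserted to overlap.
#' @return A [brain_atlas()].
#' @export
random_atlas <- function(seed, n_regions = 12, p_part = 0.25,
                         p_overlap = 0.08) {
  stopifnot(n_regions >= 1)
  with_seed(seed, {
    regs <- sprintf("R%02d", seq_len(n_regions))
    part <- list()
    for (i in seq_len(n_regions)[-1]) {
      parents <- regs[seq_len(i - 1L)]
      pick <- parents[stats::runif(length(parents)) < p_part]
      if (length(pick) > 2) pick <- sample(pick, 2)
      for (p in pick)
        part[[length(part) + 1L]] <- data.frame(child = regs[i], parent = p,
                                                stringsAsFactors = FALSE)
    }
    ov <- list()
    if (n_regions >= 2) {
      pairs <- utils::combn(regs, 2)
      keep <- stats::runif(ncol(pairs)) < p_overlap
      for (j in which(keep))
        ov[[length(ov) + 1L]] <- data.frame(a = pairs[1, j], b = pairs[2, j],
                                            stringsAsFactors = FALSE)
    }
    bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
    brain_atlas(regs,
                part_of = bind(part, data.frame(child = character(),
                                                parent = character())),
                overlaps = bind(ov, data.frame(a = character(),
                                               b = character())))
  })
}

#' Specification of a simulated tract-tracing corpus
#'
#' Knobs for [random_corpus()]: a region hierarchy of `n_regions` top-level
#' regions with subdivision chains up to `depth` levels, a ground-truth
#' connectome over the top-level regions, and noiseless observation rows
#' reporting it.  `overlap_fraction` of the injection reports describe the
#' deposit as merely overlapping the intended region (spread), exercising
#' overlap reasoning; the rest name the region or one of its parts.
#'
#' @param seed Integer seed; identical seed and knobs give an identical
#'   corpus.
#' @param n_regions Number of top-level regions (>= 2).
#' @param depth Maximum subdivision depth (1 = no subdivisions).
#' @param overlap_fraction Fraction of injection extents expressed as
#'   overlaps.
#' @param n_experiments Number of positive experiments; defaults to one per
#'   ground-truth projection, extras re-report a projection at no more than
#'   its true strength.
#' @param ground_truth Optional data frame `origin`, `termination`,
#'   `strength` over top-level regions; generated when `NULL`.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(seed, n_regions = 6, depth = 2,
                        overlap_fraction = 0.3, n_experiments = NULL,
                        ground_truth = NULL) {
  if (n_regions < 2) stop("need at least 2 regions", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(seed = seed, n_regions = n_regions, depth = depth,
                 overlap_fraction = overlap_fraction,
                 n_experiments = n_experiments,
                 ground_truth = ground_truth),
            class = "corpus_spec")
}

#' Generate a noiseless simulated tract-tracing corpus
#'
#' Builds an atlas, a ground-truth connectome over its top-level regions,
#' and an observation table in which every ground-truth projection is
#' reported by at least one experiment whose labeling density encodes the
#' true strength under the default density-to-strength map, plus distractor
#' negative (`no label`) rows.  Reporting is noiseless: running
#' [build_matrix()] over the top-level regions recovers the ground truth
#' exactly, which anchors the end-to-end recovery property tests.
#'
#' @param spec A [corpus_spec()].
#' @return List with `atlas`, `table`, `registry`, `ground_truth` (data
#'   frame `origin`, `termination`, `strength`) and `regions` (the
#'   top-level query regions).
#' @export
random_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, {
    tops <- sprintf("T%02d", seq_len(spec$n_regions))
    regions <- data.frame(abbrev = tops, name = tops, source = "simulated",
                          stringsAsFactors = FALSE)
    part <- list()
    for (t in tops) {
      parent <- t
      for (d in seq_len(spec$depth - 1L)) {
        if (stats::runif(1) > 0.6) break
        child <- sprintf("%s.%d", t, d)
        regions <- rbind(regions,
                         data.frame(abbrev = child, name = child,
                                    source = "simulated",
                                    stringsAsFactors = FALSE))
        part[[length(part) + 1L]] <- data.frame(child = child,
                                                parent = parent,
                                                stringsAsFactors = FALSE)
        parent <- child
      }
    }
    atlas <- brain_atlas(regions,
                         part_of = if (length(part)) do.call(rbind, part)
                                   else data.frame(child = character(),
                                                   parent = character()))

    truth <- spec$ground_truth
    if (is.null(truth)) {
      pairs <- expand.grid(origin = tops, termination = tops,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$origin != pairs$termination, ]
      n_proj <- min(nrow(pairs), max(2L, round(spec$n_regions * 1.2)))
      pick <- sample(nrow(pairs), n_proj)
      truth <- pairs[pick, ]
      truth$strength <- sample(c("weak", "moderate", "strong"),
                               n_proj, replace = TRUE)
      truth <- truth[order(truth$origin, truth$termination), ]
      rownames(truth) <- NULL
    }

    str2density <- c(weak = "sparse label", moderate = "moderate label",
                     strong = "dense label")
    site_extent <- function(region, allow_overlap) {
      parts <- region_descendants(atlas, region)
      target <- if (length(parts) && stats::runif(1) < 0.4)
        sample(parts, 1) else region
      if (allow_overlap && stats::runif(1) < spec$overlap_fraction)
        region_extent("overlaps", target)
      else
        region_extent("coextensive_with", target)
    }
    make_row <- function(exp_id, pub, origin, termination, density) {
      retro <- stats::runif(1) < 0.5
      inj_target <- if (retro) termination else origin
      lab_target <- if (retro) origin else termination
      data.frame(
        experiment_id = exp_id, publication = pub,
        taxonomic.class = "Rattus norvegicus",
        injection.chemical = if (retro) "tracer-R" else "tracer-A",
        injection.location = format_extent(site_extent(inj_target, TRUE)),
        mapped.location = format_extent(site_extent(lab_target, FALSE)),
        labeling.type = if (retro) "cellular" else "terminals",
        labeling.density = density,
        stringsAsFactors = FALSE)
    }

    rows <- list()
    for (i in seq_len(nrow(truth))) {
      rows[[length(rows) + 1L]] <-
        make_row(sprintf("sim-e%03d", length(rows) + 1L),
                 sprintf("sim-pub%03d", i),
                 truth$origin[i], truth$termination[i],
                 str2density[[truth$strength[i]]])
    }
    n_extra <- max(0L, (spec$n_experiments %||% nrow(truth)) - nrow(truth))
    for (k in seq_len(n_extra)) {
      i <- sample(nrow(truth), 1)
      weaker <- STRENGTH_LEVELS[seq(2L, strength_rank(truth$strength[i]))]
      rows[[length(rows) + 1L]] <-
        make_row(sprintf("sim-e%03d", length(rows) + 1L),
                 sprintf("sim-pub%03d", nrow(truth) + k),
                 truth$origin[i], truth$termination[i],
                 str2density[[sample(weaker, 1)]])
    }
    # distractor negative reports: never evidence, whatever the pair
    n_neg <- max(1L, round(nrow(truth) / 2))
    for (k in seq_len(n_neg)) {
      o <- sample(tops, 1)
      t <- sample(setdiff(tops, o), 1)
      rows[[length(rows) + 1L]] <-
        make_row(sprintf("sim-e%03d", length(rows) + 1L),
                 sprintf("sim-neg%03d", k), o, t, "no label")
    }

    list(atlas = atlas,
         table = observation_table("tract-tracing", do.call(rbind, rows)),
         registry = tracer_registry(c("tracer-A" = "anterograde",
                                      "tracer-R" = "retrograde")),
         ground_truth = truth,
         regions = tops)
  })
}
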