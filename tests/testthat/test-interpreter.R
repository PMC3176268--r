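test_that("the shipped default config maps density to strength as documented", {
  cfg <- read_interpretation_config(
    system.file("extdata", "tract-tracing-config.json", package = "kefed"))
  sc <- cfg$scale
  expect_equal(density_to_strength("no label", sc), "none")
  expect_equal(density_to_strength("very sparse label", sc), "weak")
  expect_equal(density_to_strength("moderate label", sc), "moderate")
  expect_equal(density_to_strength("dense label", sc), "strong")
  expect_equal(density_to_strength("present-unknown", sc), "weak")
  expect_error(density_to_strength("super dense", sc), "unknown density")
  expect_equal(cfg$registry[["HRP"]], "retrograde")
})

test_that("strength scales enforce totality, monotonicity and anchored endpoints", {
  dm <- kefed:::default_density_map()
  expect_s3_class(strength_scale(dm), "strength_scale")
  expect_error(strength_scale(dm[-2]), "total")
  bad <- dm; bad[["no label"]] <- "weak"
  expect_error(strength_scale(bad), "no label")
  bad <- dm; bad[["sparse label"]] <- "strong"  # drops back to moderate after
  expect_error(strength_scale(bad), "monotone")
  bad <- dm; bad[["present-unknown"]] <- "none"
  expect_error(strength_scale(bad), "positive")
})

test_that("tracer registry rejects unknown directions and unregistered chemicals", {
  expect_error(tracer_registry(c(HRP = "sideways")), "anterograde")
  wx <- worked_example()
  rows <- wx$table$rows
  rows$injection.chemical[1] <- "mystery-dye"
  expect_error(
    evidence_for_connection("CA1", "ENT",
                            observation_table("tract-tracing", rows),
                            demo_atlas(), wx$registry),
    "mystery-dye")
})

make_row <- function(pub, exp, chem, inj, lab, type, density) {
  data.frame(experiment_id = exp, publication = pub,
             taxonomic.class = "Rattus norvegicus",
             injection.chemical = chem,
             injection.location = inj, mapped.location = lab,
             labeling.type = type, labeling.density = density,
             stringsAsFactors = FALSE)
}
reg2 <- tracer_registry(c(HRP = "retrograde", "PHA-L" = "anterograde"))

test_that("the anterograde and retrograde rules gate on labeling type", {
  a <- demo_atlas()
  sc <- default_strength_scale()
  # retrograde row with axonal (fibers) label contributes nothing
  t1 <- observation_table("tract-tracing",
    make_row("p", "e1", "HRP", "coextensive_with(ENT)",
             "coextensive_with(CA1)", "fibers", "dense label"))
  expect_length(evidence_for_connection("CA1", "ENT", t1, a, reg2, sc), 0L)
  # same row with cellular label is retrograde evidence CA1 -> ENT
  t2 <- observation_table("tract-tracing",
    make_row("p", "e1", "HRP", "coextensive_with(ENT)",
             "coextensive_with(CA1)", "cellular", "dense label"))
  ev <- evidence_for_connection("CA1", "ENT", t2, a, reg2, sc)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$strength, "strong")
  expect_equal(ev[[1]]$direction_used, "retrograde")
  # anterograde accepts fibers or terminals but not cellular
  for (ty in c("fibers", "terminals")) {
    t3 <- observation_table("tract-tracing",
      make_row("p", "e1", "PHA-L", "coextensive_with(CA1)",
               "coextensive_with(ENT)", ty, "moderate label"))
    expect_length(evidence_for_connection("CA1", "ENT", t3, a, reg2, sc), 1L)
  }
  t4 <- observation_table("tract-tracing",
    make_row("p", "e1", "PHA-L", "coextensive_with(CA1)",
             "coextensive_with(ENT)", "cellular", "moderate label"))
  expect_length(evidence_for_connection("CA1", "ENT", t4, a, reg2, sc), 0L)
})

test_that("negative reports are data but never evidence", {
  a <- demo_atlas()
  t <- observation_table("tract-tracing",
    make_row("p", "e1", "HRP", "coextensive_with(ENT)",
             "coextensive_with(CA1)", "cellular", "no label"))
  expect_clean(validate_table(t, reference_model()))
  expect_length(evidence_for_connection("CA1", "ENT", t, a, reg2), 0L)
  m <- build_matrix(c("CA1", "ENT"), t, a, reg2)
  expect_equal(unname(m$strength["CA1", "ENT"]), "none")
  expect_equal(unname(m$count["CA1", "ENT"]), 0L)
})

test_that("injections into a subregion count for the enclosing region via containment", {
  a <- demo_atlas()
  t <- observation_table("tract-tracing",
    make_row("p", "e1", "PHA-L", "coextensive_with(RSPv-a)",
             "coextensive_with(POST)", "terminals", "sparse label"))
  ev <- evidence_for_connection("RSP", "POST", t, a, reg2)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$directness, "via_part")
  expect_false(ev[[1]]$injection_spread)
  expect_true(replay_trail(a, ev[[1]]$trails$injection))
  # querying the subregion itself still matches directly
  expect_equal(
    evidence_for_connection("RSPv-a", "POST", t, a, reg2)[[1]]$directness,
    "direct")
  # and an unrelated origin does not
  expect_length(evidence_for_connection("ENT", "POST", t, a, reg2), 0L)
})

test_that("overlap-matched evidence is flagged and separable with direct_only", {
  a <- demo_atlas()
  t <- observation_table("tract-tracing",
    rbind(make_row("p1", "e1", "HRP", "overlaps(ENT)|overlaps(ENTadj1)",
                   "coextensive_with(CA1)", "cellular", "present-unknown"),
          make_row("p2", "e2", "HRP", "coextensive_with(ENT)",
                   "coextensive_with(CA1)", "cellular", "present-unknown")))
  ev <- evidence_for_connection("CA1", "ENT", t, a, reg2)
  expect_length(ev, 2L)
  d <- vapply(ev, `[[`, character(1), "directness")
  expect_setequal(d, c("via_overlap", "direct"))
  spread <- vapply(ev, `[[`, logical(1), "injection_spread")
  expect_identical(sort(spread), c(FALSE, TRUE))
  ev_direct <- evidence_for_connection("CA1", "ENT", t, a, reg2,
                                       direct_only = TRUE)
  expect_length(ev_direct, 1L)
  expect_equal(ev_direct[[1]]$publication, "p2")
  # spread does not cap strength: both contribute at the mapped strength
  expect_true(all(vapply(ev, `[[`, character(1), "strength") == "weak"))
})

test_that("matrix cells aggregate by max strength with evidence counts", {
  a <- demo_atlas()
  t <- observation_table("tract-tracing",
    rbind(make_row("p1", "e1", "HRP", "coextensive_with(ENT)",
                   "coextensive_with(CA1)", "cellular", "sparse label"),
          make_row("p2", "e2", "PHA-L", "coextensive_with(CA1)",
                   "coextensive_with(ENT)", "terminals", "dense label")))
  m <- build_matrix(c("CA1", "ENT", "POST"), t, a, reg2)
  expect_equal(unname(m$strength["CA1", "ENT"]), "strong")  # max(weak, strong)
  expect_equal(unname(m$count["CA1", "ENT"]), 2L)
  # all other cells empty
  empty <- m$count; empty["CA1", "ENT"] <- 0L
  expect_true(all(empty == 0L))
  expect_true(all(m$strength[m$count == 0] == "none"))
  # drill-down matches the cell
  ev <- matrix_evidence(m, "CA1", "ENT")
  expect_length(ev, 2L)
  rep <- evidence_report(ev)
  expect_equal(kefed:::max_strength(rep$strength),
               unname(m$strength["CA1", "ENT"]))
  expect_length(matrix_evidence(m, "POST", "ENT"), 0L)
})

test_that("an empty table yields an all-none matrix and empty report", {
  a <- demo_atlas()
  t <- observation_table("tract-tracing", worked_example()$table$rows[0, ])
  m <- build_matrix(c("CA1", "ENT"), t, a, reg2)
  expect_true(all(m$strength == "none" | row(m$strength) == col(m$strength)))
  expect_true(all(m$count == 0L))
  rep <- evidence_report(list())
  expect_equal(nrow(rep), 0L)
  expect_true(all(c("publication", "strength", "directness") %in% names(rep)))
})

test_that("the provenance report is sorted and bijective with the evidence", {
  wx <- worked_example()
  ev <- evidence_for_connection("CA1", "ENT", wx$table, demo_atlas(),
                                wx$registry)
  rep <- evidence_report(ev)
  expect_equal(nrow(rep), length(ev))
  expect_equal(rep$publication, sort(rep$publication))
  expect_equal(unique(rep$publication),
               c("Beckstead-1976", "Deacon-1983", "Swanson-1977",
                 "Swanson-1981", "vanGroen-1990"))
})

test_that("connection matrices export as origin-by-termination strength:count CSV", {
  wx <- worked_example()
  m <- build_matrix(c("CA1", "ENT"), wx$table, demo_atlas(), wx$registry)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(m, tf)
  df <- utils::read.csv(tf, check.names = FALSE, colClasses = "character")
  expect_equal(names(df), c("origin", "CA1", "ENT"))
  expect_equal(df$ENT[df$origin == "CA1"], "weak:10")
  expect_equal(df$CA1[df$origin == "ENT"], "none:0")
})
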