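test_that("the reference tract-tracing model validates cleanly", {
  expect_clean(validate_model(reference_model()))
})

test_that("validation enumerates structural violations as data", {
  m <- kefed_model("bad", nodes = list(
    kefed_node("A", "activity"),
    kefed_node("B", "activity"),
    kefed_node("m1", "measurement", domain = value_domain("numeric")),
    kefed_node("p1", "parameter", domain = value_domain("free_text"))),
    edges = rbind(kefed_edge("A", "B"), kefed_edge("B", "A"),
                  kefed_edge("A", "m1", "measurement_of"),
                  kefed_edge("B", "m1", "measurement_of"),
                  kefed_edge("p1", "A", "parameter_of")))
  rep <- validate_model(m)
  expect_equal(sum(rep$check == "flow-acyclic"), 1L)
  expect_equal(sum(rep$check == "measurement-attachment"), 1L)

  # orthogonal problems each get their own row
  m2 <- kefed_model("bad2", nodes = list(
    kefed_node("A", "activity", domain = value_domain("numeric")),
    kefed_node("M", "material"),
    kefed_node("N", "material"),
    kefed_node("c1", "constant"),
    kefed_node("x", "parameter", ontology_term = "not a curie",
               domain = value_domain("ordinal", levels = "only-one"))),
    edges = rbind(kefed_edge("M", "N"),
                  kefed_edge("x", "A", "parameter_of"),
                  kefed_edge("c1", "M", "parameter_of"),
                  kefed_edge("ghost", "A")))
  rep2 <- validate_model(m2)
  expect_true(any(rep2$check == "domain" &
                    grepl("must not carry", rep2$message)))  # activity w/ domain
  expect_true(any(rep2$check == "domain" &
                    grepl("lacks a value domain", rep2$message)))  # bare constant
  expect_true(any(rep2$check == "domain" & grepl("ordinal", rep2$message)))
  expect_true(any(rep2$check == "ontology-term"))
  expect_true(any(rep2$check == "flow-edge"))        # material -> material
  expect_true(any(rep2$check == "parameter-of"))     # constant -> material
  expect_true(any(rep2$check == "edge-endpoint"))    # undeclared node
})

test_that("a one-activity model derives a one-parameter context", {
  m <- kefed_model("tiny", nodes = list(
    kefed_node("start", "material"),
    kefed_node("act", "activity"),
    kefed_node("p", "parameter", domain = value_domain("free_text")),
    kefed_node("m", "measurement", domain = value_domain("numeric"))),
    edges = rbind(kefed_edge("start", "act"),
                  kefed_edge("p", "act", "parameter_of"),
                  kefed_edge("act", "m", "measurement_of")))
  expect_clean(validate_model(m))
  expect_equal(derive_context(m, "m")$context_ids, "p")
  expect_error(derive_context(m, "nope"), "unknown node")
  expect_error(derive_context(m, "p"), "not a measurement")
})

test_that("the reference measurements are indexed by all four upstream variables", {
  m <- reference_model()
  for (meas in c("labeling.density", "labeling.type")) {
    ctx <- derive_context(m, meas)
    expect_setequal(ctx$context_ids,
                    c("taxonomic.class", "injection.chemical",
                      "injection.location", "mapped.location"))
    expect_false(anyDuplicated(ctx$context_ids) > 0)
  }
})

test_that("context is untouched by parameters on activities off the path", {
  m <- reference_model()
  # a side branch after mapping: its parameter cannot index the measurements
  nodes <- c(unname(m$nodes), list(
    kefed_node("storage", "activity", "slide storage"),
    kefed_node("storage.temp", "parameter",
               domain = value_domain("numeric", units = "C"))))
  edges <- rbind(m$edges, kefed_edge("slides", "storage"),
                 kefed_edge("storage.temp", "storage", "parameter_of"))
  m2 <- kefed_model(m$id, m$name, m$description, nodes, edges)
  expect_clean(validate_model(m2))
  expect_identical(derive_context(m2, "labeling.density"),
                   derive_context(m, "labeling.density"))
})

test_that("context derivation matches exhaustive path enumeration on random models", {
  for (seed in 1:40) {
    m <- random_kefed_model(seed)
    expect_clean(validate_model(m))
    kinds <- vapply(m$nodes, function(n) n$kind, character(1))
    for (meas in names(kinds)[kinds == "measurement"]) {
      ctx <- derive_context(m, meas)
      expect_identical(sort(ctx$context_ids), oracle_context(m, meas),
                       info = sprintf("seed %d, measurement %s", seed, meas))
      # subset of the model's variables, no duplicates
      expect_true(all(ctx$context_ids %in%
                        names(kinds)[kinds %in% c("parameter", "constant")]))
    }
  }
})

test_that("the derived form lists context variables once, then measurements", {
  form <- derive_form(reference_model())
  expect_equal(nrow(form$columns), 6L)
  expect_setequal(form$columns$node_id,
                  c("taxonomic.class", "injection.chemical",
                    "injection.location", "mapped.location",
                    "labeling.type", "labeling.density"))
  expect_equal(form$columns$role[form$columns$node_id == "taxonomic.class"],
               "constant")
  expect_true(form$columns$fixed[form$columns$node_id == "taxonomic.class"])
  expect_equal(sum(form$columns$role == "measurement"), 2L)
  # measurements come after all context columns
  expect_equal(which(form$columns$role == "measurement"), 5:6)
})

test_that("a model with no measurements derives an empty form", {
  m <- kefed_model("empty", nodes = list(
    kefed_node("s", "material"), kefed_node("a", "activity"),
    kefed_node("p", "parameter", domain = value_domain("free_text"))),
    edges = rbind(kefed_edge("s", "a"), kefed_edge("p", "a", "parameter_of")))
  expect_equal(nrow(derive_form(m)$columns), 0L)
})

test_that("measurements sharing parameters yield each parameter column once", {
  m <- reference_model()
  form <- derive_form(m)
  union_ctx <- unique(unlist(lapply(c("labeling.type", "labeling.density"),
                                    function(x)
                                      derive_context(m, x)$context_ids)))
  expect_setequal(form$columns$node_id[form$columns$role != "measurement"],
                  union_ctx)
})

test_that("model JSON round-trips and canonicalizes node order", {
  m <- reference_model()
  tf <- withr::local_tempfile(fileext = ".json")
  write_kefed_model(m, tf)
  expect_identical(read_kefed_model(tf), m)

  # permute nodes/edges on disk: same model after read
  doc <- jsonlite::read_json(tf, simplifyVector = FALSE)
  set.seed(1)
  doc$nodes <- sample(doc$nodes)
  doc$edges <- sample(doc$edges)
  tf2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, tf2, auto_unbox = TRUE)
  expect_identical(read_kefed_model(tf2), m)
})

test_that("malformed model documents fail with a pointer to the bad key", {
  tf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(id = "x", name = "x", description = "",
                            nodes = list()),
                       tf, auto_unbox = TRUE)
  expect_error(read_kefed_model(tf), "/edges")
  jsonlite::write_json(list(id = "x", name = "x", description = "",
                            nodes = list(list(kind = "activity")),
                            edges = list()),
                       tf, auto_unbox = TRUE)
  expect_error(read_kefed_model(tf), "/nodes/0")
  expect_error(write_kefed_model(
    kefed_model("bad", nodes = list(kefed_node("m", "measurement"))),
    withr::local_tempfile()), "invalid")
})
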