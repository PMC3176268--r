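test_that("the shipped demo atlas file loads to the in-code demo atlas", {
  path <- system.file("extdata", "demo-atlas.csv", package = "kefed")
  a <- load_atlas(path)
  expect_identical(a, demo_atlas())
  # the printed retrosplenial hierarchy
  expect_true(all(c("RSPd", "RSPv") %in%
                    a$part_of$child[a$part_of$parent == "RSP"]))
  expect_setequal(region_descendants(a, "RSP"),
                  c("RSPd", "RSPv", "RSPv-a", "RSPv-b/c"))
  expect_equal(nrow(a$overlaps), 0L)
})

test_that("atlas integrity errors name the offending regions", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#regions", "A,a", "B,b", "#part_of", "A,B", "B,A"), tf)
  expect_error(load_atlas(tf), "cycle.*A.*B|cycle.*B.*A")
  writeLines(c("#regions", "A,a", "#part_of", "A,Z"), tf)
  expect_error(load_atlas(tf), "undeclared.*Z")
  writeLines(c("#regions", "A,a", "#part_of", "A,A"), tf)
  expect_error(load_atlas(tf), "irreflexive")
})

test_that("an atlas with empty relation sections answers all queries false", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#regions", "A,a", "B,b", "#part_of", "#overlaps"), tf)
  a <- load_atlas(tf)
  expect_false(is_part_of(a, "A", "B"))
  expect_false(part_of_or_overlaps(a, "A", "B")$result)
  expect_true(part_of_or_overlaps(a, "A", "A")$result)  # identity only
})

test_that("duplicate and reversed overlap pairs deduplicate", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#regions", "A", "B", "#part_of", "#overlaps",
               "A,B", "B,A", "A,B"), tf)
  expect_equal(nrow(load_atlas(tf)$overlaps), 1L)
})

test_that("BAMS-style XML region exports map onto the same structures", {
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines(c('<atlas source="swanson-1998">',
               '  <region abbrev="RSP" name="retrosplenial area"/>',
               '  <region abbrev="RSPd"><name>dorsal part</name>',
               '    <parent>RSP</parent></region>',
               '  <region abbrev="RSPv" name="ventral part">',
               '    <parent>RSP</parent></region>',
               "</atlas>"), tf)
  a <- load_atlas(tf, format = "bams_xml")
  expect_setequal(a$regions$abbrev, c("RSP", "RSPd", "RSPv"))
  expect_true(is_part_of(a, "RSPd", "RSP"))
  expect_equal(a$regions$source[1], "swanson-1998")
})

test_that("proper parthood is transitive and irreflexive", {
  a <- demo_atlas()
  expect_true(is_part_of(a, "RSPv-a", "RSPv"))   # one hop
  expect_true(is_part_of(a, "RSPv-a", "RSP"))    # two hops
  expect_false(is_part_of(a, "RSP", "RSPv-a"))   # not symmetric
  expect_false(is_part_of(a, "RSP", "RSP"))      # irreflexive
  expect_error(is_part_of(a, "XX", "RSP"), "unknown region")
})

test_that("containment queries equal matrix-closure reachability on random atlases", {
  for (seed in 1:30) {
    a <- random_atlas(seed, n_regions = sample(3:14, 1))
    clo <- closure_matrix(a)
    regs <- a$regions$abbrev
    for (s in regs) for (p in regs) {
      expect_identical(is_part_of(a, s, p),
                       s != p && clo[s, p],
                       info = sprintf("seed %d: %s in %s", seed, s, p))
    }
  }
})

test_that("adding a containment pair never turns a true query false", {
  a <- random_atlas(7, n_regions = 10, p_part = 0.2)
  before <- outer(a$regions$abbrev, a$regions$abbrev,
                  Vectorize(function(s, p) is_part_of(a, s, p)))
  # add a fresh pair that cannot create a cycle (descendant-free child)
  regs <- a$regions$abbrev
  child <- setdiff(regs, a$part_of$parent)[1]
  parent <- setdiff(regs, c(child, region_descendants(a, child)))[1]
  a2 <- brain_atlas(a$regions,
                    rbind(a$part_of,
                          data.frame(child = child, parent = parent)),
                    a$overlaps)
  after <- outer(regs, regs,
                 Vectorize(function(s, p) is_part_of(a2, s, p)))
  expect_true(all(after[before]))
})

test_that("the combined relation fires its four conditions in order", {
  a <- demo_atlas()
  r <- part_of_or_overlaps(a, "RSP", "RSP")
  expect_true(r$result); expect_equal(r$trail$verdict, "identical")
  r <- part_of_or_overlaps(a, "RSPv-a", "RSP")
  expect_true(r$result); expect_equal(r$trail$verdict, "contained")

  # an extent region overlapping RSPv-a matches RSP through its part
  a2 <- brain_atlas(rbind(a$regions,
                          data.frame(abbrev = "site", name = "drawn site",
                                     source = "demo")),
                    a$part_of,
                    data.frame(a = "site", b = "RSPv-a"))
  r <- part_of_or_overlaps(a2, "site", "RSPv-a")
  expect_true(r$result); expect_equal(r$trail$verdict, "overlap")
  r <- part_of_or_overlaps(a2, "site", "RSP")
  expect_true(r$result); expect_equal(r$trail$verdict, "overlap_of_part")
  # but overlap does not climb further than one containment hop pattern:
  # 'site' overlaps nothing related to POST
  expect_false(part_of_or_overlaps(a2, "site", "POST")$result)
})

test_that("the combined relation equals brute-force evaluation on random atlases", {
  for (seed in 31:60) {
    a <- random_atlas(seed, n_regions = sample(3:14, 1), p_overlap = 0.15)
    regs <- a$regions$abbrev
    clo <- closure_matrix(a); ov <- overlaps_matrix(a)
    for (s in regs) for (p in regs) {
      got <- part_of_or_overlaps(a, s, p)
      want <- s == p || clo[s, p] || ov[s, p] ||
        any(clo[, p] & ov[s, ])
      expect_identical(got$result, want,
                       info = sprintf("seed %d: %s vs %s", seed, s, p))
      # every true answer carries a replayable trail
      if (got$result) expect_true(replay_trail(a, got$trail))
      else expect_equal(got$trail$verdict, "none")
    }
  }
})

test_that("identity and containment imply the combined relation", {
  a <- random_atlas(99, n_regions = 12)
  regs <- a$regions$abbrev
  for (s in regs) for (p in regs) {
    if (s == p || is_part_of(a, s, p))
      expect_true(part_of_or_overlaps(a, s, p)$result)
  }
})

test_that("extents resolve against targets with graded verdicts", {
  a <- demo_atlas()
  r <- resolve_extent(a, "coextensive_with(RSPv-a)", "RSP")
  expect_true(r$result)
  expect_equal(r$trail$verdict, "contained")

  r <- resolve_extent(a, "overlaps(ENT)", "ENT")
  expect_true(r$result)
  expect_equal(r$trail$verdict, "overlap")

  r <- resolve_extent(a, "overlaps(ENTl)", "ENT")  # overlaps a part
  expect_true(r$result)
  expect_equal(r$trail$verdict, "overlap_of_part")

  r <- resolve_extent(a, "part_of(ENT)", "ENT")
  expect_true(r$result)
  expect_equal(r$trail$verdict, "contained")

  r <- resolve_extent(a, "coextensive_with(ENT)", "ENT")
  expect_equal(r$trail$verdict, "identical")

  expect_false(resolve_extent(a, "coextensive_with(POST)", "ENT")$result)
  expect_error(resolve_extent(a, "coextensive_with(ZZZ)", "ENT"),
               "unknown region.*ZZZ")

  # several assertions: the most direct verdict wins
  r <- resolve_extent(a, "overlaps(ENT)|coextensive_with(ENTm)", "ENT")
  expect_equal(r$trail$verdict, "contained")
  expect_true(replay_trail(a, r$trail))
})
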