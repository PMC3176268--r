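---
title: "From experimental designs to connection evidence: the methods behind kefed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From experimental designs to connection evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kefed)
```

## The representation problem

A tract-tracing report — "injection of tracer X at site S produced labeling
of type T and density D at location L" — is only interpretable together with
its context: which animal, which chemical, where the injection actually
extended. `kefed` keeps observation and interpretation strictly apart. The
observational layer stores measurements indexed by the parameters of the
protocol that produced them; the interpretational layer applies background
knowledge (tracer transport direction, atlas geometry) to those indexed
observations and keeps a trail from every conclusion back to the rows and
reasoning steps that support it. If the background knowledge changes — a
tracer reclassified, an atlas revised — the interpretations change with it
while the observations stand.

## Workflow graphs and measurement context

A design is a DAG of materials and activities (`flow` edges), with
parameters/constants attached to activities and each measurement produced by
exactly one activity. The context of a measurement is the set of parameters
and constants attached to any activity lying on a flow path from a start
node to the producing activity.

Two derivation choices were genuinely open and are fixed as follows:

* **Branches: union over paths.** Where the workflow divides, a variable on
  *any* start-to-activity path indexes the measurement. The union is the
  conservative superset — dropping a variable that conditions only some runs
  would silently merge distinct conditions.
* **Deterministic ordering.** Sets need a presentation order for forms and
  diffs: activities in topological order of the flow graph (Kahn's algorithm
  with lexicographic tie-break), variables within an activity sorted by id.
  Re-serializing a model in any node order leaves the derived context
  identical.

Implementation note: in a finite DAG every ancestor of an activity lies on
some start-to-activity path, so the context reduces to a single reverse
reachability query rather than path enumeration. The test suite nevertheless
keeps an exhaustive path-enumeration oracle and checks agreement on hundreds
of seeded random models — the cheap formulation is an optimization, the
enumeration is the definition.

Two further modeling decisions: consecutive activities are legal in the flow
graph (a perfusion step directly follows the injection step in the reference
protocol; only material-to-material hand-offs are rejected, since a material
must be transformed by an activity), and the species constant is attached to
the first activity the subject enters, which places it in every
measurement's context without pretending variables can attach to materials.
Loops are rejected outright; repeated assays would need an indexing
construct the present context derivation cannot express.

The reference protocol asks a question the formalism deliberately leaves
open: are the injection site and the labeling location parameters or
measurements? The shipped model fixes both as parameters (they become
columns of the derived form either way), but the schema accepts the
alternative reading — nothing forbids a `region_extent`-valued measurement.

## Qualitative atlas geometry

Only two relations are stored: irreflexive transitive proper parthood and
symmetric overlap. The combined query `part_of_or_overlaps(sub, super)` is a
four-way disjunction — identity, transitive containment, direct overlap, or
overlap with a proper part of the target — evaluated in that fixed order so
that the returned trail is deterministic. Deliberately, overlap does **not**
propagate beyond the single containment hop of the fourth condition:
overlap-of-an-overlap, or overlap with an *ancestor's* sibling, implies
nothing about shared territory, and asserting it would manufacture evidence.
For the same reason nothing is auto-asserted between a region and its
parent's other children: the atlas answers exactly what its input file
declares.

Drawn extents are matched with graded verdicts, ranked
`identical > contained > overlap > overlap_of_part`; when several assertions
of one extent match, the most direct verdict is kept. An `overlaps(N)`
assertion additionally matches a target that `N` is declared to overlap —
the weakest admissible reading, ranked at the bottom and flagged like any
other overlap match.

## Interpretation rules and aggregation

* Strength is ordinal (`none < weak < moderate < strong`); a matrix cell is
  the **max** over its evidence, never a sum — counts of reports are a
  curation artifact, not a physiological quantity. The cell keeps the
  evidence count and full provenance for drill-down.
* The density-to-strength map is configuration, not code
  (`inst/extdata/tract-tracing-config.json`). Constraints enforced:
  totality over the eight density categories, `no label → none`, and
  monotonicity along the seven ordered levels. The default coarsens
  pairwise: very sparse/sparse → weak, sparse-moderate/moderate → moderate,
  moderate-dense/dense → strong.
* `present-unknown` (labeling present, density unreported) maps to the
  weakest positive strength. Discarding it would erase exactly the reports
  the category exists to keep.
* Negative reports (`no label`) are retained as data but excluded from
  evidence; a cell supported only by negative reports renders as
  (`none`, 0). Treating absence-of-label as graded evidence *against* a
  connection would require a sensitivity model the ordinal scale cannot
  carry.
* A spreading injection (extent matching more than one top-level region, or
  expressed only as overlaps) weakens evidence in the analyst's eyes, not
  arithmetically: it sets the `injection_spread` and `via_overlap` flags
  surfaced in every report, and `direct_only = TRUE` (CLI `--direct-only`)
  excludes overlap-matched evidence from the aggregation for readers who
  want the stricter matrix. Both labeling types `fibers` and `terminals`
  satisfy the anterograde rule (both are axonal label); only `cellular`
  satisfies the retrograde rule.

## What the simulator emulates — and what it does not

`random_corpus()` generates a region hierarchy, a ground-truth connectome
over its top-level regions, and observation rows reporting it: each true
projection is reported by at least one experiment (anterograde or
retrograde, chosen at random), injections land in the region or one of its
subdivisions, a configurable fraction of deposits are expressed as mere
overlaps, densities encode the true strength exactly, and distractor
negative rows are mixed in. Reporting is *noiseless* and nomenclature is
*uniform* — so exact recovery of the ground truth by `build_matrix()` is the
correct expectation and is what the property tests assert.

Real corpora break both idealizations: studies disagree on parcellation,
densities are judged by eye, extents are under-described, and negative
evidence is under-reported. Passing the recovery property therefore shows
the *pipeline* is faithful (whatever is encoded is read back, through
whichever geometric route), not that curation noise is handled — the package
surfaces disagreement in the per-cell evidence table and leaves adjudication
to the analyst.

Problem sizes used by the checked-in tests and the acceptance script: 200
random models for the context oracle, 200 random atlases (≤ 15 regions, all
ordered pairs) for the spatial oracle, 50 corpora (5 top-level regions,
depth 2, 30 % overlapping deposits) for recovery, and 3 corpora for the
direction-symmetry invariant; the full suite runs in about a minute.

## Degenerate inputs and edge behaviour

Empty relation files yield atlases where every containment query is false
and only identity satisfies the combined relation. A model without
measurements derives an empty form. An empty observation table yields an
all-`none` matrix. Duplicate and reversed overlap pairs deduplicate
(unordered pairs are stored normalized). Containment cycles, undeclared
regions in a pair, and reflexive pairs are load-time errors naming the
offenders, not warnings.

## Known limitations

* Macroconnections only: region-pair granularity, no laminar patterns, cell
  populations or synapse counts.
* No statistical aggregation across contexts; the matrix is max-and-count,
  and conflicting reports are surfaced rather than reconciled.
* Ontology annotation is a stored CURIE string; no terminology service is
  consulted.
* The worked example's overlapping injection extents name synthetic
  neighbor regions (`ENTadj1..3`), because the sources identify the spilled
  territory only as "other areas"; they are placeholders, marked as such in
  the atlas, and nothing downstream depends on their identity.
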