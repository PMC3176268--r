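# kefed

Knowledge engineering from experimental design, applied to rat-brain
connectivity: represent a tract-tracing protocol as a typed workflow graph,
derive the parameter context of every measurement by tracing data
dependencies, curate observations against the derived data form, reason
qualitatively over a brain-region atlas, and interpret the observations as an
evidence-backed matrix of ordinal connection strengths.

## Who this is for

Biocurators and neuroinformaticians who extract tract-tracing results from
the literature and want (a) each data point stored with its full experimental
context rather than as a bare assertion, and (b) connectivity claims that can
be drilled down to the observations — and the spatial reasoning — that
support them.

## The model

**Experimental designs** are directed acyclic graphs of *materials*,
*activities* and control-flow nodes, with variables attached: *parameters*
and *constants* condition an activity (`parameter_of` edges), *measurements*
are produced by one activity (`measurement_of` edges). A measurement made at
activity *A* is indexed by every parameter or constant attached to an
activity on some flow path from a start node to *A* (union over paths when
the workflow branches). That index set is the measurement's *context*, and
the union of contexts plus the measurements is the data-entry form derived
automatically from the design.

**Atlas reasoning** works over two relations between named regions:
irreflexive, transitive proper parthood (`PROPER-PART-OF`) and symmetric
overlap (`OVERLAPS`). The combined query used throughout is

```
part-of-or-overlaps(sub, super) :=
      sub = super
   ∨  proper-part-of⁺(sub, super)
   ∨  overlaps(sub, super)
   ∨  ∃ r . proper-part-of⁺(r, super) ∧ overlaps(sub, r)
```

with a reasoning trail recording which condition fired. Injection sites and
labeling patches are *region extents* — qualified relations
(`coextensive_with`, `proper_part_of`, `overlaps`) to named regions —
resolved against a target region through the same machinery.

**Interpretation**: an anterograde tracer travels from cell bodies to axon
terminals, a retrograde tracer the reverse. A row is evidence for the
projection origin → termination if either the anterograde rule (anterograde
injection matching the origin, `fibers`/`terminals` labeling matching the
termination) or the retrograde rule (retrograde injection matching the
termination, `cellular` labeling matching the origin) applies. The reported
labeling density (a seven-point ordinal scale plus `present-unknown`) maps
monotonically onto connection strengths `none < weak < moderate < strong`;
a matrix cell shows the strongest connection for which any evidence exists,
with the count and the full provenance behind it.

## Worked example

The package ships a curated example: ten data points from five publications
bearing on the projection from hippocampal field CA1 to the entorhinal area
(ENT).

```r
library(kefed)

model <- reference_model()
derive_context(model, "labeling.density")
#> context(labeling.density): {injection.chemical, injection.location,
#>                             taxonomic.class, mapped.location}

wx <- worked_example()
ev <- evidence_for_connection("CA1", "ENT", wx$table, demo_atlas(),
                              wx$registry, default_strength_scale())
evidence_report(ev)[, c("publication", "experiment_id", "strength", "directness")]
#>       publication experiment_id strength  directness
#> 1  Beckstead-1976  beckstead-e1     weak      direct
#> 2  Beckstead-1976  beckstead-e2     weak    via_part
#> 3  Beckstead-1976  beckstead-e3     weak    via_part
#> 4     Deacon-1983     deacon-e1     weak via_overlap
#> 5     Deacon-1983     deacon-e2     weak via_overlap
#> 6     Deacon-1983     deacon-e3     weak via_overlap
#> 7    Swanson-1977  swanson77-e1     weak      direct
#> 8    Swanson-1981  swanson81-e1     weak      direct
#> 9   vanGroen-1990   vangroen-e1     weak      direct
#> 10  vanGroen-1990   vangroen-e2     weak      direct
```

Reading the table: the two Beckstead injections into the ENT subdivisions
ENTl/ENTm count for ENT through containment (`via_part`); the three Deacon
deposits merely overlapped ENT, so they match only through overlap reasoning
(`via_overlap`) and are flagged as spreading injections; every density is
`present-unknown` (the sources report presence only), which enters at the
weakest positive strength. Aggregated:

```r
m <- build_matrix(c("CA1", "ENT"), wx$table, demo_atlas(), wx$registry)
m
#> <connection_matrix> 2 x 2 regions, 1 cells with evidence
#>     CA1    ENT
#> CA1 -      weak:10
#> ENT none:0 -
```

All ten reports support CA1 → ENT; none support the reverse direction.

A command-line wrapper over the same functions is installed at
`system.file("cli", "kefed", package = "kefed")`, with subcommands
`model validate|form`, `data validate`, `atlas validate`,
`matrix build|evidence` and `fixtures export`.

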