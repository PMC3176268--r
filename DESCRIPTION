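Package: kefed
Title: Experimental-Design Knowledge Models and Tract-Tracing Connectivity Reasoning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for representing experimental protocols as typed workflow
    graphs (the KEfED formalism: activities, materials, parameters, constants
    and measurements), deriving the parameter context of every measurement by
    tracing data dependencies, and validating observation tables against the
    derived data forms.  On top of this, a qualitative spatial-reasoning layer
    over brain-region atlases (transitive proper parthood, overlaps, and the
    combined part-of-or-overlaps relation with reasoning trails) and a
    rule-based interpreter that turns anterograde/retrograde tract-tracing
    observations into an evidence-backed matrix of ordinal connection
    strengths with drill-down provenance.  Includes a reference tract-tracing
    model, a hippocampal demo atlas, a curated worked example, and seeded
    generators of random models, atlases and corpora for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    xml2,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
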