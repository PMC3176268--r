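{
  "id": "tract-tracing",
  "name": "generic tract-tracing experiment",
  "description": "Generic anterograde/retrograde tract-tracing protocol: injection, perfusion, sectioning, immunostaining, neuroanatomical mapping.",
  "nodes": [
    {
      "id": "brain",
      "kind": "material",
      "label": "dissected brain",
      "ontology_term": "fma:FMA_50801"
    },
    {
      "id": "immunostaining",
      "kind": "activity",
      "label": "immunohistochemistry",
      "ontology_term": "nif:nlx_inv_20090609"
    },
    {
      "id": "injection",
      "kind": "activity",
      "label": "tracer injection",
      "ontology_term": "obi:OBI_0000426"
    },
    {
      "id": "injection.chemical",
      "kind": "parameter",
      "label": "injection chemical",
      "domain": {
        "kind": "free_text"
      }
    },
    {
      "id": "injection.location",
      "kind": "parameter",
      "label": "injection location",
      "domain": {
        "kind": "region_extent"
      }
    },
    {
      "id": "labeling.density",
      "kind": "measurement",
      "label": "labeling density",
      "domain": {
        "kind": "ordinal",
        "levels": [
          "no label",
          "very sparse label",
          "sparse label",
          "sparse/moderate label",
          "moderate label",
          "moderate/dense label",
          "dense label",
          "present-unknown"
        ]
      }
    },
    {
      "id": "labeling.type",
      "kind": "measurement",
      "label": "labeling type",
      "domain": {
        "kind": "nominal",
        "levels": [
          "cellular",
          "fibers",
          "terminals"
        ]
      }
    },
    {
      "id": "mapped.location",
      "kind": "parameter",
      "label": "labeling location",
      "domain": {
        "kind": "region_extent"
      }
    },
    {
      "id": "mapping",
      "kind": "activity",
      "label": "neuroanatomical mapping and analysis",
      "ontology_term": "obi:OBI_0600020"
    },
    {
      "id": "perfusion",
      "kind": "activity",
      "label": "perfusion",
      "ontology_term": "obi:OBI_0000919"
    },
    {
      "id": "sectioning",
      "kind": "activity",
      "label": "tissue sectioning",
      "ontology_term": "nif:birnlex_2156"
    },
    {
      "id": "sections",
      "kind": "material",
      "label": "tissue sections",
      "ontology_term": "nif:birnlex_2169"
    },
    {
      "id": "slides",
      "kind": "material",
      "label": "immunostained slides"
    },
    {
      "id": "subject",
      "kind": "material",
      "label": "experimental subject",
      "ontology_term": "obi:OBI_0100026"
    },
    {
      "id": "taxonomic.class",
      "kind": "constant",
      "label": "taxonomic class",
      "domain": {
        "kind": "free_text"
      }
    }
  ],
  "edges": [
    {
      "source": "brain",
      "target": "sectioning",
      "kind": "flow"
    },
    {
      "source": "immunostaining",
      "target": "slides",
      "kind": "flow"
    },
    {
      "source": "injection",
      "target": "perfusion",
      "kind": "flow"
    },
    {
      "source": "injection.chemical",
      "target": "injection",
      "kind": "parameter_of"
    },
    {
      "source": "injection.location",
      "target": "injection",
      "kind": "parameter_of"
    },
    {
      "source": "mapped.location",
      "target": "mapping",
      "kind": "parameter_of"
    },
    {
      "source": "mapping",
      "target": "labeling.density",
      "kind": "measurement_of"
    },
    {
      "source": "mapping",
      "target": "labeling.type",
      "kind": "measurement_of"
    },
    {
      "source": "perfusion",
      "target": "brain",
      "kind": "flow"
    },
    {
      "source": "sectioning",
      "target": "sections",
      "kind": "flow"
    },
    {
      "source": "sections",
      "target": "immunostaining",
      "kind": "flow"
    },
    {
      "source": "slides",
      "target": "mapping",
      "kind": "flow"
    },
    {
      "source": "subject",
      "target": "injection",
      "kind": "flow"
    },
    {
      "source": "taxonomic.class",
      "target": "injection",
      "kind": "parameter_of"
    }
  ]
}
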