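{
  "version": "sc-1.0",
  "sections": {
    "sample": [
      { "name": "alias", "tier": "mandatory", "value_kind": "text" },
      { "name": "material", "tier": "mandatory", "value_kind": "text",
        "allowed_values": ["organism", "specimen"] },
      { "name": "organism", "tier": "mandatory", "value_kind": "ontology_term",
        "when": { "material": "organism" } },
      { "name": "sex", "tier": "mandatory", "value_kind": "text",
        "allowed_values": ["male", "female"],
        "when": { "material": "organism" } },
      { "name": "breed", "tier": "recommended", "value_kind": "text",
        "when": { "material": "organism" } },
      { "name": "birth_date", "tier": "optional", "value_kind": "date",
        "when": { "material": "organism" } },
      { "name": "specimen_tissue", "tier": "mandatory", "value_kind": "ontology_term",
        "when": { "material": "specimen" } },
      { "name": "derived_from", "tier": "mandatory", "value_kind": "entity_ref",
        "refers_to": "sample", "when": { "material": "specimen" } },
      { "name": "health_status", "tier": "recommended", "value_kind": "text",
        "when": { "material": "specimen" } },
      { "name": "collection_date", "tier": "optional", "value_kind": "date",
        "when": { "material": "specimen" } }
    ],
    "experiment": [
      { "name": "alias", "tier": "mandatory", "value_kind": "text" },
      { "name": "assay_type", "tier": "mandatory", "value_kind": "text",
        "allowed_values": ["scRNA-seq", "scATAC-seq"] },
      { "name": "library_construction", "tier": "mandatory", "value_kind": "text" },
      { "name": "sample_ref", "tier": "mandatory", "value_kind": "entity_ref",
        "refers_to": "sample" },
      { "name": "sequencing_instrument", "tier": "recommended", "value_kind": "text" },
      { "name": "insert_size", "tier": "optional", "value_kind": "number" }
    ],
    "analysis": [
      { "name": "alias", "tier": "mandatory", "value_kind": "text" },
      { "name": "file_name", "tier": "mandatory", "value_kind": "file_ref" },
      { "name": "file_type", "tier": "mandatory", "value_kind": "text",
        "allowed_values": ["fastq", "bam", "mtx", "h5ad"] },
      { "name": "checksum", "tier": "mandatory", "value_kind": "text" },
      { "name": "experiment_ref", "tier": "mandatory", "value_kind": "entity_ref",
        "refers_to": "experiment" },
      { "name": "analysis_protocol", "tier": "recommended", "value_kind": "text" },
      { "name": "analysis_date", "tier": "optional", "value_kind": "date" }
    ]
  }
}
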