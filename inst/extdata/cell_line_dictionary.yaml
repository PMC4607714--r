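# Minimal cell-line dictionary: token -> candidate identities.  Identifiers
# are carried as opaque strings.  'H4' is the classic ambiguous token: the
# same name denotes both a rat hepatoma and a human neuroglioma line, and
# only organism context can resolve it.
schema_version: 1
cell_lines:
  H4:
    - {organism: "Rattus norvegicus", identity: "rat hepatoma cell line", ontology_id: "ATCC:CRL-1548"}
    - {organism: "Homo sapiens", identity: "human neuroglioma cell line", ontology_id: "ATCC:HTB-148"}
  HepG2:
    - {organism: "Homo sapiens", identity: "human hepatocellular carcinoma cell line", ontology_id: "ATCC:HB-8065"}
  3T3-L1:
    - {organism: "Mus musculus", identity: "mouse embryonic fibroblast (adipocyte differentiation)", ontology_id: "ATCC:CL-173"}
  CHO-K1:
    - {organism: "Cricetulus griseus", identity: "Chinese hamster ovary cell line", ontology_id: "ATCC:CCL-61"}
  MCF7:
    - {organism: "Homo sapiens", identity: "human breast adenocarcinoma cell line", ontology_id: "ATCC:HTB-22"}
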