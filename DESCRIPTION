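Package: sarclean
Title: Standardisation and Quality Flagging of Literature Bioactivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates heterogeneous published bioactivity records the way
    large medicinal-chemistry databases do before each release: activity
    types and units are normalised to canonical standards (nM, ug/mL,
    ng.h/mL), logarithmic endpoints are unlogged, values are rounded by
    a two-tier significant-figure rule, and records are flagged for
    missing data, non-standard units, out-of-range values (with a
    fragment exception), cross-publication citation duplicates and
    1000-fold or 10^6-fold unit transcription errors. Computes pChEMBL
    values for clean dose-response records, classifies assays by type
    and BioAssay Ontology format with rule-based keyword cascades, and
    validates target component invariants. Includes a seeded generator
    of messy literature-style corpora with per-record ground truth so
    every flagging rule can be evaluated by precision and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    RSQLite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
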