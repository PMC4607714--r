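# small fixture builders shared across test files

make_records <- function(...) {
  rows <- list(...)
  base <- tibble::tibble(
    record_id = paste0("r", seq_along(rows)),
    document_id = "d1", assay_id = "a1", compound_id = "c1",
    published_type = "IC50", published_relation = "=",
    published_value = NA_real_, published_units = NA_character_
  )
  base <- activity_records(base)   # adds the optional columns as NA
  for (i in seq_along(rows)) {
    for (nm in names(rows[[i]])) base[[nm]][i] <- rows[[i]][[nm]]
  }
  base
}

one_assay <- function(assay_id = "a1", target_id = "t1",
                      document_id = "d1",
                      description = "Binding affinity") {
  assay_records(tibble::tibble(
    assay_id = assay_id, document_id = document_id,
    description = description, target_id = target_id))
}

one_compound <- function(compound_id = "c1", mw = 450) {
  compound_records(tibble::tibble(compound_id = compound_id,
                                  molecular_weight = mw))
}

# members tibble for the redundancy detectors
make_members <- function(values, docs, years = NULL) {
  years <- years %||% (2000L + as.integer(factor(docs, levels = unique(docs))))
  tibble::tibble(
    group_id = 1L,
    record_id = paste0("m", seq_along(values)),
    document_id = docs, document_year = as.integer(years),
    standard_value = values
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# config with range flagging disabled (ranges are opt-in)
config_no_ranges <- function() {
  cfg <- curation_config()
  cfg$typical_ranges <- cfg$typical_ranges[0, ]
  cfg
}
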