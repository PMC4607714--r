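# validity flagging: missing data, non-standard units, out-of-range values.
# Flags never delete or reorder records, and a record carries at most one
# data-validity comment -- earlier workflow steps take precedence, so every
# flagger skips records that already carry a comment.

set_comment <- function(records, mask, comment) {
  mask <- mask & is.na(records$data_validity_comment)
  records$data_validity_comment[mask] <- comment
  records
}

#' Flag records with no activity at all
#'
#' A record is potentially missing data when it has neither a published
#' activity value nor an activity comment (a comment such as 'Not active'
#' is itself an informative outcome, so commented records are not flagged).
#'
#' @param records Activity tibble.
#' @return The records, with `data_validity_comment` set to
#'   'Potential missing data' where the rule fires; existing comments are
#'   never overwritten.
#' @export
flag_missing <- function(records) {
  r <- activity_records(records)
  mask <- is.na(r$published_value) &
    (is.na(r$activity_comment) | !nzchar(trimws(r$activity_comment)))
  set_comment(r, mask, "Potential missing data")
}

#' Flag irrelevant, unknown or null units for an activity type
#'
#' After standardisation, each standard type accepts a small set of
#' canonical units (e.g. nM for Ki).  Records whose standard units fall
#' outside that set -- including records with no units at all -- are
#' flagged.  Types with no allowed-unit entry are not policed (the table
#' is opt-in).
#'
#' @param records Activity tibble (standardised).
#' @param config A [curation_config()].
#' @return Records with 'Non standard unit for type' comments applied.
#' @export
flag_nonstandard_units <- function(records, config = curation_config()) {
  r <- activity_records(records)
  allowed <- config$allowed_units
  policed <- chr_in(r$standard_type, names(allowed))
  unit_ok <- as.logical(mapply(
    function(u, ty) !is.na(u) && !is.na(ty) && u %in% allowed[[ty]],
    r$standard_units, r$standard_type,
    USE.NAMES = FALSE
  ))
  mask <- policed & !unit_ok
  set_comment(r, mask, "Non standard unit for type")
}

#' Flag unusually low or high activity values
#'
#' Compares each standardised value against an inclusive typical range for
#' its (type, unit) pair -- the shipped table uses the stringent
#' 0.01 nM to 100 uM window for dose-response endpoints.  Binding
#' affinities measured on fragments (MW below the configured threshold,
#' default 350 Da) are expected to be genuinely weak, so the upper bound
#' is relaxed by a multiplicative factor for them.  Pairs with no range
#' entry are never flagged.
#'
#' @param records Activity tibble (standardised).
#' @param compounds Compound tibble with molecular weights; compounds with
#'   unknown MW are treated as non-fragments.
#' @param config A [curation_config()].
#' @return Records with 'Outside typical range' comments applied.
#' @export
flag_out_of_range <- function(records, compounds,
                              config = curation_config()) {
  r <- activity_records(records)
  cmp <- compound_records(compounds)
  mw <- cmp$molecular_weight[match(r$compound_id, cmp$compound_id)]

  rng <- config$typical_ranges
  idx <- match(paste(r$standard_type, r$standard_units, sep = "\r"),
               paste(rng$standard_type, rng$standard_units, sep = "\r"))
  low <- rng$low[idx]
  high <- rng$high[idx]

  fragment <- !is.na(mw) & mw < config$fragment_mw_threshold
  upper <- ifelse(fragment, high * config$fragment_range_relaxation, high)

  mask <- !is.na(r$standard_value) & !is.na(idx) &
    (r$standard_value < low | r$standard_value > upper)
  set_comment(r, mask, "Outside typical range")
}
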