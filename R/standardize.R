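# standardization: published type/relation/value/units -> canonical
# standard forms.  Published fields are never mutated; all standard fields
# are recomputed from them, so the step is idempotent by construction.

#' Normalise a published activity type
#'
#' Maps the many published spellings of an activity type ('Half life',
#' 'half-life', 't(1/2)', ...) onto one canonical standard type via the
#' synonym table, after case/whitespace/punctuation normalisation.  Types
#' with no synonym entry are returned as their trimmed input.
#'
#' @param published_type Character vector of published types.
#' @param config A [curation_config()].
#' @return Character vector of standard types.
#' @examples
#' normalize_type(c("Half life", "t(1/2)", "IC50"))
#' @export
normalize_type <- function(published_type, config = curation_config()) {
  key <- normalize_type_key(published_type)
  idx <- match(key, config$type_lookup$key)
  out <- config$type_lookup$standard_type[idx]
  fallback <- is.na(out) & !is.na(published_type)
  out[fallback] <- trimws(published_type[fallback])
  out
}

# TRUE where the (normalized) published type is a declared logarithmic type
is_log_type <- function(published_type, config) {
  normalize_type_key(published_type) %in% config$log_types$key
}

# '<' <-> '>' and '<=' <-> '>=' ; '=' and '~' are their own mirror
flip_relation <- function(relation) {
  flipped <- c("<" = ">", "<=" = ">=", "=" = "=", ">=" = "<=", ">" = "<",
               "~" = "~")
  out <- unname(flipped[relation])
  out[is.na(relation)] <- NA_character_
  out
}

#' Convert published units to the canonical standard unit
#'
#' Looks each published unit up in the conversion-dialect table: molar
#' concentration dialects map to nM, mass-per-volume dialects to
#' `ug.mL-1`, exposure (AUC) dialects to `ng.h.mL-1` and durations to
#' `hr`, each via a multiplicative factor.  The relation is untouched.
#' Unrecognised units -- and non-positive values in a concentration class,
#' which cannot be physical concentrations -- fail conversion: the value
#' and units pass through unchanged with `ok = FALSE`, to be picked up by
#' the non-standard-unit flagging step.  No cross-dimension conversion
#' (mass to molar via MW) is attempted.
#'
#' @param value,relation,published_units Parallel vectors describing the
#'   published quantity.
#' @param standard_type Character vector of (already normalised) types;
#'   carried through to the output.
#' @param config A [curation_config()].
#' @return Tibble with `ok`, `standard_type`, `standard_relation`,
#'   `standard_value`, `standard_units`.
#' @examples
#' convert_units(1, "=", "uM", "IC50")
#' @export
convert_units <- function(value, relation, published_units, standard_type,
                          config = curation_config()) {
  n <- max(length(value), length(relation), length(published_units),
           length(standard_type))
  value <- rep_len(as.numeric(value), n)
  relation <- rep_len(as.character(relation), n)
  published_units <- rep_len(as.character(published_units), n)
  standard_type <- rep_len(as.character(standard_type), n)

  idx <- match(normalize_unit_key(published_units),
               config$unit_conversions$key)
  cls <- config$unit_conversions$class[idx]
  fac <- config$unit_conversions$factor[idx]
  std_unit <- config$unit_conversions$standard_unit[idx]

  conc <- c("concentration", "mass_concentration", "exposure")
  ok <- !is.na(idx) & !is.na(value) &
    !(cls %in% conc & value <= 0)

  tibble(
    ok = ok,
    standard_type = standard_type,
    standard_relation = relation,
    standard_value = ifelse(ok, value * fac, value),
    standard_units = ifelse(ok, std_unit, published_units)
  )
}

#' Unlog a logarithmic activity value
#'
#' Converts log-scale endpoints (pKi, pIC50, logIC50, ...) to their linear
#' standard value in nM.  Negative-log types antilog as `10^(-x)` on the
#' declared reference scale (M by default) and flip censored relations
#' (`pKi > 6` means `Ki < 1000 nM`); plain-log types antilog as `10^x` and
#' keep the relation.  The type is renamed to its linear counterpart
#' (pKi -> Ki).  Unknown log types pass through untouched (`ok = FALSE`).
#'
#' @param standard_type Character vector of (normalised) published types.
#' @param value,relation Parallel numeric/character vectors.
#' @param config A [curation_config()].
#' @return Tibble with `ok`, `standard_type`, `standard_relation`,
#'   `standard_value`, `standard_units`.
#' @examples
#' unlog_value("pKi", 9, "=")
#' unlog_value("pKi", 6, ">")
#' @export
unlog_value <- function(standard_type, value, relation,
                        config = curation_config()) {
  n <- max(length(standard_type), length(value), length(relation))
  standard_type <- rep_len(as.character(standard_type), n)
  value <- rep_len(as.numeric(value), n)
  relation <- rep_len(as.character(relation), n)

  idx <- match(normalize_type_key(standard_type), config$log_types$key)
  ok <- !is.na(idx) & !is.na(value)
  negated <- config$log_types$negated[idx]
  scale_nm <- ifelse(config$log_types$scale[idx] == "nM", 1, 1e9)
  linear <- config$log_types$linear_type[idx]

  out_value <- ifelse(ok,
                      ifelse(negated, 10^(-value), 10^value) * scale_nm,
                      value)
  out_rel <- ifelse(ok & negated, flip_relation(relation), relation)

  tibble(
    ok = ok,
    standard_type = ifelse(ok, linear, standard_type),
    standard_relation = out_rel,
    standard_value = out_value,
    standard_units = ifelse(ok, "nM", NA_character_)
  )
}

#' Standardise activity records
#'
#' Recomputes every `standard_*` field from the published fields: the type
#' is normalised through the synonym table, logarithmic types are unlogged
#' to nM, linear types have their units converted within their dimension
#' class, and the resulting value is rounded by the two-tier rule
#' ([round_standard_value()]).  Published fields are preserved verbatim so
#' users can always map a record back to its publication; records without
#' a published value get no standard fields at all.  Standard fields,
#' comments, duplicate flags and pChEMBL values present in the input are
#' reset (they are downstream products).
#'
#' @param records Activity tibble (see [activity_records()]).
#' @param config A [curation_config()].
#' @return The records with standard fields populated (or NA on conversion
#'   failure, with units/value passed through for the unit flagger), plus
#'   attribute `n_log_converted`: how many records were unlogged.
#' @export
standardize_activities <- function(records, config = curation_config()) {
  r <- activity_records(records)
  r$standard_type <- NA_character_
  r$standard_relation <- NA_character_
  r$standard_value <- NA_real_
  r$standard_units <- NA_character_
  r$pchembl_value <- NA_real_
  r$data_validity_comment <- NA_character_
  r$potential_duplicate <- FALSE

  has_value <- !is.na(r$published_value)
  std_type <- normalize_type(r$published_type, config)
  logish <- is_log_type(r$published_type, config) & has_value

  if (any(logish)) {
    u <- unlog_value(std_type[logish], r$published_value[logish],
                     r$published_relation[logish], config)
    r$standard_type[logish] <- u$standard_type
    r$standard_relation[logish] <- u$standard_relation
    r$standard_value[logish] <- u$standard_value
    r$standard_units[logish] <- u$standard_units
  }

  lin <- has_value & !logish
  if (any(lin)) {
    cv <- convert_units(r$published_value[lin], r$published_relation[lin],
                        r$published_units[lin], std_type[lin], config)
    r$standard_type[lin] <- cv$standard_type
    r$standard_relation[lin] <- cv$standard_relation
    r$standard_value[lin] <- cv$standard_value
    r$standard_units[lin] <- cv$standard_units
  }

  r$standard_value <- round_standard_value(r$standard_value)
  attr(r, "n_log_converted") <- sum(logish)
  r
}
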