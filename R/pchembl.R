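# pChEMBL: negative log10 of a dose-response activity in molar units,
# computed only for clean, exact, positive nM measurements of the eligible
# endpoint family.

#' Compute pChEMBL values
#'
#' `pChEMBL = -log10(value in M) = 9 - log10(value in nM)`, rounded to two
#' decimals.  A value is produced only when the standard type is in the
#' eligible dose-response set (IC50, XC50, EC50, AC50, Ki, Kd, Potency by
#' default), the units are nM, the relation is an exact '=' (a censored
#' bound has no point estimate to take a log of, and '~' is excluded), the
#' value is positive, and the record carries no data-validity comment.
#' The `potential_duplicate` flag is *not* a validity comment and does not
#' suppress the value.
#'
#' @param standard_type,standard_relation,standard_value,standard_units
#'   Parallel vectors describing the standardised quantity (value in nM).
#' @param data_validity_comment Optional parallel character vector.
#' @param config A [curation_config()].
#' @return Numeric vector: the pChEMBL value, or NA where ineligible.
#' @examples
#' compute_pchembl("IC50", "=", 1000, "nM")
#' compute_pchembl("IC50", ">", 1000, "nM")  # censored: NA
#' @export
compute_pchembl <- function(standard_type, standard_relation, standard_value,
                            standard_units,
                            data_validity_comment = NA_character_,
                            config = curation_config()) {
  n <- max(length(standard_type), length(standard_relation),
           length(standard_value), length(standard_units),
           length(data_validity_comment))
  standard_type <- rep_len(as.character(standard_type), n)
  standard_relation <- rep_len(as.character(standard_relation), n)
  standard_value <- rep_len(as.numeric(standard_value), n)
  standard_units <- rep_len(as.character(standard_units), n)
  data_validity_comment <- rep_len(as.character(data_validity_comment), n)

  eligible <- chr_in(standard_type, config$pchembl_types) &
    chr_in(standard_relation, "=") &
    chr_in(standard_units, "nM") &
    !is.na(standard_value) & standard_value > 0 &
    is.na(data_validity_comment)

  out <- rep(NA_real_, n)
  out[eligible] <- round_half_up(9 - log10(standard_value[eligible]), 2)
  out
}

#' Add pChEMBL values to an activity table
#'
#' @param records Standardised, flagged activity tibble.
#' @param config A [curation_config()].
#' @return Records with `pchembl_value` populated where eligible.
#' @export
add_pchembl <- function(records, config = curation_config()) {
  r <- activity_records(records)
  r$pchembl_value <- compute_pchembl(
    r$standard_type, r$standard_relation, r$standard_value,
    r$standard_units, r$data_validity_comment, config)
  r
}
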