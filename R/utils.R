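# internal string/number helpers shared across modules

# half-up ("arithmetic") rounding at a fixed number of decimal digits.
# A relative epsilon absorbs binary representation error so that decimal
# halves like 1.005 round up even though their double is slightly below.
round_half_up <- function(x, digits) {
  f <- 10^digits
  y <- x * f
  sign(y) * floor(abs(y) + 0.5 + abs(y) * 1e-12) / f
}

# half-up rounding to k significant figures
signif_half_up <- function(x, k) {
  out <- x
  nz <- !is.na(x) & x != 0
  if (any(nz)) {
    e <- floor(log10(abs(x[nz])))
    out[nz] <- round_half_up(x[nz], k - 1 - e)
  }
  out
}

#' Round a standard activity value
#'
#' Applies the two-tier arithmetic rounding rule used for standardised
#' activity values: values with magnitude lower than 10 are rounded half-up
#' to 3 significant figures; all other values are rounded half-up to the
#' second decimal digit.
#'
#' @param x Numeric vector of standard values (NA passed through).
#' @return Numeric vector of rounded values.
#' @examples
#' round_standard_value(c(1.23456, 123.456, 0.0123456))
#' @export
round_standard_value <- function(x) {
  out <- x
  ok <- !is.na(x)
  small <- ok & abs(x) < 10
  out[small] <- signif_half_up(x[small], 3)
  out[ok & !small] <- round_half_up(x[ok & !small], 2)
  out
}

# canonical key for activity-type lookup: case-folded, punctuation and
# whitespace stripped ('t(1/2)' and 'T1/2' collide as intended); a leading
# minus sign is kept so '-logKd' and 'logKd' stay distinct
normalize_type_key <- function(x) {
  x <- tolower(trimws(x))
  gsub("[^a-z0-9%+-]", "", x)
}

# canonical key for unit lookup: case-folded, micro sign unified to 'u',
# separators ('.', '*', unicode middle dots/times, spaces) collapsed away,
# '/' and '-' kept so 'mL-1' and '/ml' spellings remain distinct entries
normalize_unit_key <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("µ|μ", "u", x)
  x <- gsub("[ .*'’×·⋅]", "", x)
  x
}

# strict %in% for possibly-NA character vectors: NA never matches
chr_in <- function(x, set) !is.na(x) & x %in% set

new_id <- function(prefix, i, width = 6) {
  sprintf("%s%0*d", prefix, width, i)
}
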