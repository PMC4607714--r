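#' Load a curation configuration
#'
#' Reads the rule tables that drive the whole pipeline: activity-type
#' synonyms, logarithmic-type declarations, unit-conversion dialects,
#' allowed units per standard type, typical activity ranges (with the
#' fragment relaxation), the pChEMBL-eligible type set, transcription-error
#' decades and the assay keyword cascades.  With no argument the
#' configuration shipped with the package is loaded.
#'
#' @param path Path to a YAML configuration file; `NULL` for the packaged
#'   default.
#' @return A list of class `curation_config`; rule tables are tibbles.
#' @examples
#' cfg <- curation_config()
#' cfg$fragment_mw_threshold
#' @export
curation_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "curation_config.yaml",
                                package = "sarclean")
  raw <- yaml::read_yaml(path)

  syn <- raw$type_synonyms %||% list()
  type_lookup <- tibble(
    key = unlist(lapply(names(syn), function(std) {
      normalize_type_key(c(std, unlist(syn[[std]])))
    }), use.names = FALSE),
    standard_type = rep(names(syn),
                        vapply(syn, function(s) length(unlist(s)) + 1L,
                               integer(1)))
  ) |> distinct(.data$key, .keep_all = TRUE)

  log_types <- bind_rows(lapply(raw$log_types %||% list(), as_tibble))
  if (nrow(log_types)) {
    log_types$key <- normalize_type_key(log_types$published_type)
  } else {
    log_types <- tibble(published_type = character(), linear_type = character(),
                        negated = logical(), scale = character(),
                        key = character())
  }

  conv <- bind_rows(lapply(raw$unit_conversions %||% list(), function(e) {
    e$factor <- as.numeric(e$factor)   # YAML floats like 1.0e9 arrive as text
    as_tibble(e)
  }))
  if (nrow(conv)) {
    conv$key <- normalize_unit_key(conv$pattern)
    conv <- distinct(conv, .data$key, .keep_all = TRUE)
  } else {
    conv <- tibble(pattern = character(), class = character(),
                   factor = double(), standard_unit = character(),
                   key = character())
  }

  ranges <- bind_rows(lapply(raw$typical_ranges %||% list(), function(e) {
    e$low <- as.numeric(e$low); e$high <- as.numeric(e$high)
    as_tibble(e)
  }))
  if (!nrow(ranges)) {
    ranges <- tibble(standard_type = character(), standard_units = character(),
                     low = double(), high = double())
  }

  cfg <- structure(list(
    schema_version = raw$schema_version %||% 1L,
    type_lookup = type_lookup,
    log_types = log_types,
    unit_conversions = conv,
    allowed_units = lapply(raw$allowed_units %||% list(), unlist),
    typical_ranges = ranges,
    fragment_mw_threshold = raw$fragment_mw_threshold %||% 350,
    fragment_range_relaxation = raw$fragment_range_relaxation %||% 100,
    pchembl_types = unlist(raw$pchembl_types %||% character()),
    transcription_decades = as.numeric(unlist(raw$transcription_decades %||% c(3, 6))),
    assay_type_rules = lapply(raw$assay_type_rules %||% list(), unlist),
    bao_format_rules = lapply(raw$bao_format_rules %||% list(), unlist)
  ), class = "curation_config")
  validate_config(cfg)
  cfg
}

#' Validate a curation configuration
#'
#' Checks the structural invariants of the rule tables: positive conversion
#' factors, well-ordered typical ranges (`low < high`), and pChEMBL types
#' covered by the allowed-unit table.  Errors on the first violation.
#'
#' @param config A `curation_config` object.
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "curation_config"))
  if (nrow(config$unit_conversions) &&
      any(config$unit_conversions$factor <= 0)) {
    abort("unit_conversions: all factors must be > 0")
  }
  r <- config$typical_ranges
  if (nrow(r) && any(r$low >= r$high)) {
    abort("typical_ranges: every range must have low < high")
  }
  missing_types <- setdiff(config$pchembl_types, names(config$allowed_units))
  if (length(missing_types)) {
    abort(paste0("pchembl_types not present in allowed_units: ",
                 paste(missing_types, collapse = ", ")))
  }
  if (config$fragment_mw_threshold <= 0 ||
      config$fragment_range_relaxation < 1) {
    abort("fragment rule: threshold must be > 0 and relaxation >= 1")
  }
  if (!all(config$transcription_decades == round(config$transcription_decades)) ||
      any(config$transcription_decades <= 0)) {
    abort("transcription_decades must be positive integers")
  }
  invisible(config)
}

#' Load a cell-line dictionary
#'
#' @param path Path to a YAML dictionary; `NULL` for the packaged default.
#' @return Named list mapping cell-line tokens to tibbles of candidate
#'   identities (organism, identity, ontology_id).
#' @export
cell_line_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cell_line_dictionary.yaml",
                                package = "sarclean")
  raw <- yaml::read_yaml(path)
  lapply(raw$cell_lines %||% list(),
         function(entries) bind_rows(lapply(entries, as_tibble)))
}

#' @export
print.curation_config <- function(x, ...) {
  cat("<curation_config> schema", x$schema_version, "\n")
  cat("  type synonyms:   ", nrow(x$type_lookup), "spellings ->",
      length(unique(x$type_lookup$standard_type)), "standard types\n")
  cat("  log types:       ", nrow(x$log_types), "\n")
  cat("  unit dialects:   ", nrow(x$unit_conversions), "(",
      paste(sprintf("%s: %d", names(table(x$unit_conversions$class)),
                    as.integer(table(x$unit_conversions$class))),
            collapse = ", "), ")\n")
  cat("  typical ranges:  ", nrow(x$typical_ranges),
      "| fragment MW <", x$fragment_mw_threshold,
      "relaxes upper bound x", x$fragment_range_relaxation, "\n")
  cat("  pChEMBL types:   ", paste(x$pchembl_types, collapse = ", "), "\n")
  invisible(x)
}
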