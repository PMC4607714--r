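# records model: canonical tibble layouts for activities, compounds, assays
# and targets, plus structural validators.  Validation never raises; it
# returns a tibble of violations (empty when all invariants hold).

ACTIVITY_COLUMNS <- c(
  "record_id", "document_id", "document_year", "assay_id", "compound_id",
  "published_type", "published_relation", "published_value",
  "published_units", "activity_comment", "standard_type",
  "standard_relation", "standard_value", "standard_units", "pchembl_value",
  "data_validity_comment", "potential_duplicate"
)

#' Build an activity-record table
#'
#' Coerces a data frame of measurement rows into the canonical activity
#' layout: published fields exactly as extracted from a publication,
#' standard fields as produced by the pipeline, one optional data-validity
#' comment and a separate duplicate flag.  Absent columns are added as NA.
#'
#' @param x A data frame with at least `record_id`, `document_id`,
#'   `assay_id`, `compound_id`, `published_type`, `published_relation`,
#'   `published_value`, `published_units`.
#' @return A tibble with the full activity column set, original row order
#'   preserved.
#' @export
activity_records <- function(x) {
  x <- as_tibble(x)
  required <- c("record_id", "document_id", "assay_id", "compound_id",
                "published_type", "published_relation", "published_value",
                "published_units")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  defaults <- list(
    document_year = NA_integer_, activity_comment = NA_character_,
    standard_type = NA_character_, standard_relation = NA_character_,
    standard_value = NA_real_, standard_units = NA_character_,
    pchembl_value = NA_real_, data_validity_comment = NA_character_,
    potential_duplicate = FALSE
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(x)) x[[nm]] <- defaults[[nm]]
  }
  x$published_value <- as.numeric(x$published_value)
  x$standard_value <- as.numeric(x$standard_value)
  x$document_year <- as.integer(x$document_year)
  x$potential_duplicate <- !is.na(x$potential_duplicate) & as.logical(x$potential_duplicate)
  x[, union(ACTIVITY_COLUMNS, names(x))]
}

#' Validate activity records
#'
#' Checks the record-level invariants: a present standard value implies
#' standard units and type (unless the record is flagged 'Non standard unit
#' for type'); a pChEMBL value implies no data-validity comment; relations
#' and comments are drawn from their closed vocabularies.  Total: never
#' raises, returns one row per violation.
#'
#' @param records Activity tibble (see [activity_records()]).
#' @return Tibble with columns `record_id`, `field`, `violation`.
#' @examples
#' bad <- activity_records(tibble::tibble(
#'   record_id = "r1", document_id = "d1", assay_id = "a1",
#'   compound_id = "c1", published_type = "IC50", published_relation = "=",
#'   published_value = 5, published_units = "nM",
#'   pchembl_value = 8.3, data_validity_comment = "Outside typical range"))
#' validate_activity_records(bad)
#' @export
validate_activity_records <- function(records) {
  r <- activity_records(records)
  v <- list()
  bad_rel <- function(rel) !is.na(rel) & !rel %in% RELATIONS

  hit <- function(mask, field, violation) {
    if (any(mask)) {
      tibble(record_id = r$record_id[mask], field = field,
             violation = violation)
    }
  }

  v$comment <- hit(
    !is.na(r$data_validity_comment) &
      !r$data_validity_comment %in% DATA_VALIDITY_COMMENTS,
    "data_validity_comment", "unknown data validity comment")
  v$std <- hit(
    !is.na(r$standard_value) &
      (is.na(r$standard_units) | is.na(r$standard_type)) &
      (is.na(r$data_validity_comment) |
         r$data_validity_comment != "Non standard unit for type"),
    "standard_value",
    "standard_value present without standard_units/standard_type")
  v$pchembl <- hit(
    !is.na(r$pchembl_value) & !is.na(r$data_validity_comment),
    "pchembl_value", "pchembl_value present alongside a data validity comment")
  v$prel <- hit(bad_rel(r$published_relation),
                "published_relation", "relation outside vocabulary")
  v$srel <- hit(bad_rel(r$standard_relation),
                "standard_relation", "relation outside vocabulary")

  out <- bind_rows(v)
  if (!nrow(out)) {
    out <- tibble(record_id = character(), field = character(),
                  violation = character())
  }
  out
}

#' Build a compound table
#'
#' @param x Data frame with `compound_id` and optionally `molecular_weight`
#'   (Daltons; must be positive when present).
#' @return Tibble with `compound_id`, `molecular_weight`.
#' @export
compound_records <- function(x) {
  x <- as_tibble(x)
  if (!"compound_id" %in% names(x)) abort("missing required column(s): compound_id")
  if (!"molecular_weight" %in% names(x)) x$molecular_weight <- NA_real_
  x$molecular_weight <- as.numeric(x$molecular_weight)
  bad <- !is.na(x$molecular_weight) & x$molecular_weight <= 0
  if (any(bad)) {
    abort(paste0("non-positive molecular_weight for: ",
                 paste(x$compound_id[bad], collapse = ", ")))
  }
  x
}

#' Build an assay table
#'
#' @param x Data frame with `assay_id`, `document_id`, `description`;
#'   optional `assay_type` (B/F/A/T/P), `bao_format`, `relationship_type`
#'   (D = direct, H = homologue, U = unassigned), `target_id`,
#'   `cell_line_token`, `therapeutic_context`.
#' @return Tibble in the canonical assay layout.
#' @export
assay_records <- function(x) {
  x <- as_tibble(x)
  required <- c("assay_id", "document_id", "description")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  defaults <- list(
    assay_type = NA_character_, bao_format = "unassigned",
    relationship_type = "U", target_id = NA_character_,
    cell_line_token = NA_character_, therapeutic_context = FALSE
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(x)) x[[nm]] <- defaults[[nm]]
  }
  bad <- !is.na(x$assay_type) & !x$assay_type %in% ASSAY_TYPES
  if (any(bad)) {
    abort(paste0("assay_type outside {B,F,A,T,P} for: ",
                 paste(x$assay_id[bad], collapse = ", ")))
  }
  x
}

#' Build a target table
#'
#' Targets carry the biological-complexity taxonomy: a SINGLE PROTEIN has
#' exactly one component; PROTEIN FAMILY (subtype unresolved), PROTEIN
#' COMPLEX (multi-subunit) and PROTEIN COMPLEX GROUP (complex of unresolved
#' composition) each span two or more components.  The binding subunit,
#' when annotated, must itself be a component.
#'
#' @param x Data frame with `target_id`, `target_type` and `components`
#'   (a list-column of character vectors, or a `;`/`,`-separated string),
#'   optional `binding_component`.
#' @return Tibble with a `components` list-column.
#' @export
target_records <- function(x) {
  x <- as_tibble(x)
  required <- c("target_id", "target_type", "components")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (!is.list(x$components)) {
    x$components <- strsplit(as.character(x$components), "[;,]\\s*")
  }
  if (!"binding_component" %in% names(x)) x$binding_component <- NA_character_
  x
}

#' Validate target records
#'
#' Component-count and membership rules per target type, e.g. a pentameric
#' receptor assembled from unresolved alpha/beta/gamma subunits is a valid
#' PROTEIN COMPLEX GROUP with >= 2 components.  Never raises.
#'
#' @param targets Target tibble (see [target_records()]).
#' @return Tibble with columns `target_id`, `field`, `violation`.
#' @export
validate_target_records <- function(targets) {
  t <- target_records(targets)
  n_comp <- vapply(t$components, function(cc) length(cc[!is.na(cc) & nzchar(cc)]),
                   integer(1))
  multi <- c("PROTEIN FAMILY", "PROTEIN COMPLEX", "PROTEIN COMPLEX GROUP")
  v <- list(
    type = tibble(target_id = t$target_id,
                  field = "target_type",
                  violation = "unknown target type")[
                    !is.na(t$target_type) & !t$target_type %in% TARGET_TYPES, ],
    single = tibble(target_id = t$target_id,
                    field = "components",
                    violation = "SINGLE PROTEIN must have exactly 1 component")[
                      chr_in(t$target_type, "SINGLE PROTEIN") & n_comp != 1L, ],
    multi = tibble(target_id = t$target_id,
                   field = "components",
                   violation = "family/complex targets must have >= 2 components")[
                     chr_in(t$target_type, multi) & n_comp < 2L, ],
    binding = tibble(target_id = t$target_id,
                     field = "binding_component",
                     violation = "binding_component not among components")[
                       !is.na(t$binding_component) &
                         !mapply(function(b, cc) b %in% cc,
                                 t$binding_component, t$components), ]
  )
  out <- bind_rows(v)
  if (!nrow(out)) {
    out <- tibble(target_id = character(), field = character(),
                  violation = character())
  }
  out
}
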