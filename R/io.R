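# file IO: CSV/TSV readers with typed parsing and a rejects report, a
# lossless curated-records writer, the JSON curation report, and an
# optional SQLite convenience reader.

parse_numeric_column <- function(x, column, ids) {
  raw <- trimws(as.character(x))
  raw[!nzchar(raw)] <- NA_character_
  val <- suppressWarnings(as.numeric(raw))
  bad <- !is.na(raw) & is.na(val)
  rejects <- tibble(record_id = ids[bad], column = column, raw = raw[bad])
  list(value = val, rejects = rejects)
}

read_table_auto <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = c("", "NA"),
    progress = FALSE, show_col_types = FALSE)
}

#' Read activity records from CSV/TSV
#'
#' Column names are lower-snake-case versions of the production schema
#' (`published_value`, `standard_type`, ...).  Empty cells become absent
#' values.  Malformed numeric cells (including locale-ambiguous comma
#' decimals like "12,5") are not guessed: the value becomes NA and the
#' cell is recorded in the rejects report attached as attribute
#' `rejects`.  A missing required column is a hard error naming it.
#'
#' @param path CSV (or `.tsv`) file with a header.
#' @return Activity tibble; `attr(, "rejects")` holds a tibble of
#'   rejected cells (`record_id`, `column`, `raw`).
#' @export
read_activities <- function(path) {
  x <- read_table_auto(path)
  required <- c("record_id", "document_id", "assay_id", "compound_id",
                "published_type", "published_relation", "published_value",
                "published_units")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  rejects <- list()
  for (col in intersect(c("published_value", "standard_value",
                          "pchembl_value", "document_year"), names(x))) {
    p <- parse_numeric_column(x[[col]], col, x$record_id)
    x[[col]] <- p$value
    rejects[[col]] <- p$rejects
  }
  if ("potential_duplicate" %in% names(x)) {
    x$potential_duplicate <- tolower(x$potential_duplicate) %in%
      c("true", "t", "1", "yes")
  }
  out <- activity_records(x)
  attr(out, "rejects") <- bind_rows(rejects) %||%
    tibble(record_id = character(), column = character(), raw = character())
  out
}

#' Read a compound table from CSV/TSV
#' @param path File with `compound_id` and optional `molecular_weight`.
#' @return Compound tibble (rejects for malformed MW cells as attribute).
#' @export
read_compounds <- function(path) {
  x <- read_table_auto(path)
  if (!"compound_id" %in% names(x)) {
    abort("missing required column(s): compound_id")
  }
  rejects <- tibble(record_id = character(), column = character(),
                    raw = character())
  if ("molecular_weight" %in% names(x)) {
    p <- parse_numeric_column(x$molecular_weight, "molecular_weight",
                              x$compound_id)
    x$molecular_weight <- p$value
    rejects <- p$rejects
  }
  out <- compound_records(x)
  attr(out, "rejects") <- rejects
  out
}

#' Read an assay table from CSV/TSV
#' @param path File with `assay_id`, `document_id`, `description` and
#'   optional annotation columns.
#' @return Assay tibble.
#' @export
read_assays <- function(path) {
  x <- read_table_auto(path)
  if ("therapeutic_context" %in% names(x)) {
    x$therapeutic_context <- tolower(x$therapeutic_context) %in%
      c("true", "t", "1", "yes")
  }
  assay_records(x)
}

#' Write curated records to CSV
#'
#' Row order and every published field are preserved verbatim, so the
#' output can be read back losslessly and re-curated as a no-op.
#'
#' @param records Curated activity tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curated <- function(records, path) {
  r <- activity_records(records)[, ACTIVITY_COLUMNS]
  readr::write_csv(r, path, na = "")
  invisible(path)
}

#' Write the curation report as JSON
#'
#' @param report Report tibble from [curate()] / [curation_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read activity, compound and assay tables from a SQLite file
#'
#' Convenience reader for a minimal SQLite database using the same table
#' and column names as the CSV dialect (`activities`, `compounds`,
#' `assays`).  Requires the RSQLite package.
#'
#' @param path SQLite file.
#' @return List with `records`, `compounds`, `assays` tibbles.
#' @export
read_corpus_sqlite <- function(path) {
  if (!requireNamespace("RSQLite", quietly = TRUE)) {
    abort("read_corpus_sqlite() requires the RSQLite package")
  }
  con <- RSQLite::dbConnect(RSQLite::SQLite(), path)
  on.exit(RSQLite::dbDisconnect(con))
  list(
    records = activity_records(RSQLite::dbReadTable(con, "activities")),
    compounds = compound_records(RSQLite::dbReadTable(con, "compounds")),
    assays = assay_records(RSQLite::dbReadTable(con, "assays"))
  )
}
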