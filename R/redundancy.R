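# redundancy detection: cross-publication citation duplicates and unit
# transcription errors.  Records are compared like-for-like after
# standardisation, grouped by (compound, target, standard type, standard
# units); within a group only records from DIFFERENT documents can match
# (two measurements in one paper -- e.g. a racemate and its isolated
# stereoisomers -- are legitimate repeats, never flagged).

# rounding-aware value equality: exact match, or one value equals the other
# rounded to 1, 2 or 3 significant figures (either direction) -- published
# citations are typically truncations of the original measurement
values_match <- function(a, b, tol = 1e-9) {
  near <- function(x, y) {
    (x == y) | abs(x - y) <= tol * pmax(abs(x), abs(y))
  }
  m <- near(a, b)
  for (k in 1:3) {
    m <- m | near(a, signif_half_up(b, k)) | near(signif_half_up(a, k), b)
  }
  m
}

# document order: year ascending, unknown year last (so an undated citation
# is flagged rather than the dated original), ties by lexicographic id
doc_rank <- function(document_id, document_year) {
  ord <- order(is.na(document_year), document_year, document_id)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  rank
}

#' Group standardised records for redundancy comparison
#'
#' Duplicate citations and transcription errors are only meaningful among
#' records measuring the same thing in the same currency, so records are
#' keyed by (compound, target, standard type, standard units); the target
#' is resolved through the record's assay.  Records lacking any key
#' component or a standard value cannot be compared and are skipped (their
#' count is kept in attribute `n_skipped`).
#'
#' @param records Standardised activity tibble.
#' @param assays Assay tibble carrying `assay_id` -> `target_id`.
#' @return Tibble of group members: `group_id`, the four key columns, and
#'   `record_id`, `document_id`, `document_year`, `standard_value`.
#' @export
build_match_groups <- function(records, assays) {
  r <- activity_records(records)
  a <- assay_records(assays)
  r$target_id <- a$target_id[match(r$assay_id, a$assay_id)]

  usable <- !is.na(r$compound_id) & !is.na(r$target_id) &
    !is.na(r$standard_type) & !is.na(r$standard_units) &
    !is.na(r$standard_value)
  g <- r[usable, c("compound_id", "target_id", "standard_type",
                   "standard_units", "record_id", "document_id",
                   "document_year", "standard_value")]
  g <- g |>
    group_by(.data$compound_id, .data$target_id, .data$standard_type,
             .data$standard_units) |>
    mutate(group_id = cur_group_id()) |>
    ungroup() |>
    relocate("group_id")
  attr(g, "n_skipped") <- sum(!usable)
  g
}

# pairwise cross-document match matrix for one group's values
cross_doc_pairs <- function(members) {
  n <- nrow(members)
  if (n < 2) return(NULL)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  keep <- members$document_id[i] != members$document_id[j]
  cbind(i = i[keep], j = j[keep])
}

#' Detect duplicate citation records in one match group
#'
#' Two records from different documents are treated as the same underlying
#' measurement when their standard values are equal or related by rounding
#' to 1--3 significant figures (a cited value is often a rounded copy of
#' the original).  Matches are closed transitively into clusters; within a
#' cluster every record except those from the earliest document (year
#' ascending, ties by document id, unknown years last) is a potential
#' duplicate.  Same-document repeats never match.
#'
#' @param members One group from [build_match_groups()] (tibble with
#'   `record_id`, `document_id`, `document_year`, `standard_value`).
#' @return Character vector of flagged `record_id`s.
#' @export
detect_duplicates <- function(members) {
  pairs <- cross_doc_pairs(members)
  if (is.null(pairs)) return(character())
  hit <- values_match(members$standard_value[pairs[, "i"]],
                      members$standard_value[pairs[, "j"]])
  if (!any(hit)) return(character())

  # union-find over matched pairs
  parent <- seq_len(nrow(members))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in which(hit)) {
    ri <- find(pairs[p, "i"]); rj <- find(pairs[p, "j"])
    if (ri != rj) parent[rj] <- ri
  }
  comp <- vapply(seq_len(nrow(members)), find, integer(1))
  rank <- doc_rank(members$document_id, members$document_year)

  flagged <- logical(nrow(members))
  for (cl in unique(comp)) {
    ids <- which(comp == cl)
    if (length(ids) < 2) next
    earliest_doc <- members$document_id[ids[which.min(rank[ids])]]
    flagged[ids] <- members$document_id[ids] != earliest_doc
  }
  members$record_id[flagged]
}

#' Detect unit transcription errors in one match group
#'
#' A mis-citation with wrong units shows up as an otherwise matching pair
#' of records from different documents whose values differ by exactly 3 or
#' 6 orders of magnitude (e.g. a Ki quoted in uM instead of nM).  The
#' larger value is divided by the decade offset and the pair is compared
#' with the same rounding-aware match used for duplicates; the record from
#' the later publication is flagged.  Nothing below a 1000-fold offset
#' qualifies.
#'
#' @param members One group from [build_match_groups()].
#' @param decades Decade offsets that count as unit slips (default `c(3, 6)`).
#' @return Character vector of flagged `record_id`s.
#' @export
detect_transcription_errors <- function(members, decades = c(3, 6)) {
  pairs <- cross_doc_pairs(members)
  if (is.null(pairs)) return(character())
  vi <- members$standard_value[pairs[, "i"]]
  vj <- members$standard_value[pairs[, "j"]]
  big <- pmax(vi, vj); small <- pmin(vi, vj)

  hit <- rep(FALSE, nrow(pairs))
  for (k in decades) {
    scaled <- big / 10^k
    # stored values are standard-rounded, so a decade-scaled copy of a
    # rounded value re-rounds (195659.34 / 1000 -> 195.66); compare the
    # re-rounded mantissa too
    hit <- hit | values_match(scaled, small, tol = 1e-6) |
      values_match(round_standard_value(scaled), small, tol = 1e-6)
  }
  if (!any(hit)) return(character())

  rank <- doc_rank(members$document_id, members$document_year)
  later <- ifelse(rank[pairs[, "i"]] > rank[pairs[, "j"]],
                  pairs[, "i"], pairs[, "j"])
  unique(members$record_id[later[hit]])
}

#' Apply duplicate and transcription-error flags to a corpus
#'
#' Orchestrates grouping, per-group detection and write-back.  Duplicate
#' citations set the separate `potential_duplicate` flag (they are
#' legitimate values, just not independent evidence); transcription errors
#' set the 'Potential transcription error' validity comment, without
#' overwriting a comment from an earlier step.  Record count and order are
#' conserved.
#'
#' @param records Standardised activity tibble.
#' @param assays Assay tibble.
#' @param config A [curation_config()] (supplies the decade offsets).
#' @return Records with flags applied; attributes `n_duplicate`,
#'   `n_transcription` (comments applied) and `transcription_ids` (all
#'   detected ids, before comment precedence).
#' @export
apply_redundancy_flags <- function(records, assays,
                                   config = curation_config()) {
  r <- activity_records(records)
  groups <- build_match_groups(r, assays)

  dup_ids <- character()
  trans_ids <- character()
  if (nrow(groups)) {
    multi <- groups |> add_count(.data$group_id) |> filter(.data$n > 1)
    for (members in split(multi, multi$group_id)) {
      dup_ids <- c(dup_ids, detect_duplicates(members))
      trans_ids <- c(trans_ids,
                     detect_transcription_errors(
                       members, config$transcription_decades))
    }
  }

  r$potential_duplicate <- r$potential_duplicate | r$record_id %in% dup_ids
  newly <- r$record_id %in% trans_ids & is.na(r$data_validity_comment)
  r <- set_comment(r, r$record_id %in% trans_ids,
                   "Potential transcription error")
  attr(r, "n_duplicate") <- sum(r$record_id %in% dup_ids)
  attr(r, "n_transcription") <- sum(newly)
  attr(r, "transcription_ids") <- unique(trans_ids)
  r
}
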