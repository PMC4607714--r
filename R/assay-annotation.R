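# rule-based assay annotation: a deterministic keyword surrogate for expert
# curation.  Keyword lists live in the config; precedence between tiers is
# fixed, order within a tier is irrelevant (any-match).

match_any <- function(description, keywords) {
  if (!length(keywords)) return(rep(FALSE, length(description)))
  d <- tolower(description)
  Reduce(`|`, lapply(tolower(keywords),
                     function(k) grepl(k, d, fixed = TRUE)))
}

#' Assign an assay type
#'
#' Classifies an assay description into one of the five categories:
#' B (binding), F (functional), A (ADME), T (toxicity), P
#' (physicochemical).  The categories overlap, so precedence applies:
#' ADME keywords dominate (a cytochrome P450 binding assay is more useful
#' filed under ADME than under binding); physicochemical keywords yield P
#' only with no biological-target context; cytotoxicity reads as
#' functional when the assay is run as an efficacy model (e.g. anti-cancer,
#' signalled by `therapeutic_context`) and as toxicity otherwise; binding
#' keywords yield B; everything else defaults to functional.
#'
#' @param description Character vector of assay descriptions (non-empty).
#' @param therapeutic_context Logical vector: is the assay an efficacy
#'   model?  Recycled.
#' @param config A [curation_config()].
#' @return Character vector of codes in `{B, F, A, T, P}`.
#' @examples
#' assign_assay_type("Inhibition of cytochrome P450 3A4")
#' assign_assay_type("Cytotoxicity against HepG2 cells",
#'                   therapeutic_context = c(TRUE, FALSE))
#' @export
assign_assay_type <- function(description, therapeutic_context = FALSE,
                              config = curation_config()) {
  n <- max(length(description), length(therapeutic_context))
  description <- rep_len(as.character(description), n)
  therapeutic_context <- rep_len(as.logical(therapeutic_context), n)
  rules <- config$assay_type_rules

  adme <- match_any(description, rules$adme)
  phys <- match_any(description, rules$physicochemical) &
    !match_any(description, rules$biological_context)
  cytotox <- match_any(description, rules$cytotoxicity)
  tox <- match_any(description, rules$toxicity)
  bind <- match_any(description, rules$binding)

  out <- rep("F", n)
  out[bind] <- "B"
  out[tox & !bind] <- "T"
  out[cytotox] <- ifelse(therapeutic_context[cytotox], "F", "T")
  out[phys] <- "P"
  out[adme] <- "A"
  out
}

#' Classify the assay format (BioAssay Ontology classes)
#'
#' Ordered rule cascade over the description: whole-organism cues win, then
#' tissue/organ cues (an isolated guinea pig ileum preparation is
#' tissue-based even though cells are present), then cell cues (or an
#' extracted cell-line token), then isolated-protein cues; otherwise the
#' format stays unassigned.  More complex systems subsume simpler cues,
#' hence the precedence.
#'
#' @param description Character vector of assay descriptions.
#' @param cell_line_token Optional parallel character vector: a cell-line
#'   name extracted from the description forces at least cell-based.
#' @param config A [curation_config()].
#' @return Character vector in `{biochemical, cell-based, tissue-based,
#'   organism-based, unassigned}`.
#' @examples
#' classify_bao_format("Contraction of guinea pig ileum")
#' classify_bao_format("Cytotoxicity", cell_line_token = "3T3-L1")
#' @export
classify_bao_format <- function(description, cell_line_token = NA_character_,
                                config = curation_config()) {
  n <- max(length(description), length(cell_line_token))
  description <- rep_len(as.character(description), n)
  cell_line_token <- rep_len(as.character(cell_line_token), n)
  rules <- config$bao_format_rules

  out <- rep("unassigned", n)
  out[match_any(description, rules$biochemical)] <- "biochemical"
  out[!is.na(cell_line_token) & nzchar(cell_line_token) |
        match_any(description, rules[["cell-based"]])] <- "cell-based"
  out[match_any(description, rules[["tissue-based"]])] <- "tissue-based"
  out[match_any(description, rules[["organism-based"]])] <- "organism-based"
  out
}

#' Annotate an assay table
#'
#' Applies [assign_assay_type()] and [classify_bao_format()] to every row.
#'
#' @param assays Assay tibble (see [assay_records()]).
#' @param config A [curation_config()].
#' @return The assays with `assay_type` and `bao_format` filled in.
#' @export
annotate_assays <- function(assays, config = curation_config()) {
  a <- assay_records(assays)
  a$assay_type <- assign_assay_type(a$description, a$therapeutic_context,
                                    config)
  a$bao_format <- classify_bao_format(a$description, a$cell_line_token,
                                      config)
  a
}

#' Look up a cell-line token and report ambiguity
#'
#' Some cell-line names are reused across organisms ('H4' names both a rat
#' hepatoma and a human neuroglioma line); such tokens need organism
#' context before they can be mapped to an ontology entry.
#'
#' @param token A single cell-line token.
#' @param dictionary A dictionary from [cell_line_dictionary()].
#' @return A list with `token`, `status` ('unknown', 'unambiguous' or
#'   'ambiguous') and `candidates` (tibble of identities, empty when
#'   unknown).
#' @examples
#' flag_ambiguous_cell_line("H4")
#' @export
flag_ambiguous_cell_line <- function(token,
                                     dictionary = cell_line_dictionary()) {
  stopifnot(length(token) == 1)
  candidates <- dictionary[[token]]
  if (is.null(candidates)) {
    candidates <- tibble(organism = character(), identity = character(),
                         ontology_id = character())
  }
  status <- if (!nrow(candidates)) "unknown"
  else if (nrow(candidates) == 1) "unambiguous"
  else "ambiguous"
  list(token = token, status = status, candidates = candidates)
}
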