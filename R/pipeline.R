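# pipeline orchestration: the seven-step automated curation workflow over
# standardised records, plus the per-step report and result methods.

STEP_NAMES <- c(
  "Flag missing activities",
  "Flag non-standard units for activity type",
  "Convert log activity values",
  "Flag out of range values",
  "Flag potential duplicate values",
  "Flag potential transcription errors",
  "Calculate standard negative log values"
)

STEP_COMMENTS <- c(
  "Potential missing data", "Non standard unit for type", NA,
  "Outside typical range", NA, "Potential transcription error", NA
)

#' Run the automated activity curation workflow
#'
#' Standardises every record (type normalisation, unlogging, unit
#' conversion, two-tier rounding) and then applies the seven curation
#' steps in order: (1) flag missing activities, (2) flag non-standard
#' units, (3) log conversion (performed during standardisation, counted
#' here), (4) flag out-of-range values with the fragment exception,
#' (5) flag cross-publication duplicate citations, (6) flag decade
#' transcription errors, (7) compute pChEMBL for clean dose-response
#' records.  Records are only ever flagged, never deleted or reordered,
#' and published fields are preserved verbatim; re-running the pipeline on
#' its own output reproduces it exactly.
#'
#' @param records Activity tibble (see [activity_records()]).
#' @param compounds Compound tibble (molecular weights for the fragment
#'   rule); may be missing columns for unknown compounds.
#' @param assays Assay tibble (resolves each record's target for
#'   duplicate/transcription grouping).
#' @param config A [curation_config()].
#' @return An object of class `curation_result`: list with `records` (the
#'   curated tibble), `report` (the per-step [curation_report()]) and
#'   `config`.
#' @examples
#' corpus <- generate_corpus(corpus_params(n_compounds = 10, n_targets = 2,
#'                                         n_documents = 6, seed = 7))
#' res <- curate(corpus$records, corpus$compounds, corpus$assays)
#' res$report
#' @export
curate <- function(records, compounds, assays, config = curation_config()) {
  n <- nrow(as_tibble(records))
  counts <- integer(7)

  r <- standardize_activities(records, config)
  counts[3] <- attr(r, "n_log_converted")

  count_new <- function(before, after) {
    sum(is.na(before$data_validity_comment) &
          !is.na(after$data_validity_comment))
  }

  r2 <- flag_missing(r);                       counts[1] <- count_new(r, r2)
  r3 <- flag_nonstandard_units(r2, config);    counts[2] <- count_new(r2, r3)
  r4 <- flag_out_of_range(r3, compounds, config); counts[4] <- count_new(r3, r4)
  r5 <- apply_redundancy_flags(r4, assays, config)
  counts[5] <- attr(r5, "n_duplicate")
  counts[6] <- attr(r5, "n_transcription")
  r6 <- add_pchembl(r5, config)
  counts[7] <- sum(!is.na(r6$pchembl_value))
  for (a in c("n_log_converted", "n_duplicate", "n_transcription",
              "transcription_ids", "rejects", "n_skipped")) {
    attr(r6, a) <- NULL
  }

  report <- curation_report(counts, n)
  structure(list(records = r6, report = report, config = config),
            class = "curation_result")
}

#' Build a per-step curation report
#'
#' One row per workflow step with the validity comment it writes (NA for
#' the standardisation and pChEMBL steps), the number of affected records
#' and their percentage of the corpus.
#'
#' @param counts Integer vector of length 7: affected records per step.
#' @param corpus_size Total record count.
#' @return Tibble with `step`, `name`, `data_validity_comment`, `count`,
#'   `percentage`.
#' @export
curation_report <- function(counts, corpus_size) {
  stopifnot(length(counts) == 7, all(counts >= 0))
  tibble(
    step = 1:7,
    name = STEP_NAMES,
    data_validity_comment = STEP_COMMENTS,
    count = as.integer(counts),
    percentage = if (corpus_size > 0) 100 * counts / corpus_size else
      rep(0, 7)
  )
}

#' @export
print.curation_result <- function(x, ...) {
  cat("<curation_result>", nrow(x$records), "records curated\n\n")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

#' Tidy a curation result
#'
#' @param x A `curation_result`.
#' @param ... Unused.
#' @return The per-step report tibble.
#' @method tidy curation_result
#' @export
tidy.curation_result <- function(x, ...) x$report

#' One-row summary of a curation result
#'
#' @param x A `curation_result`.
#' @param ... Unused.
#' @return Tibble with corpus size, per-flag counts, duplicate count and
#'   pChEMBL coverage.
#' @method glance curation_result
#' @export
glance.curation_result <- function(x, ...) {
  r <- x$records
  tibble(
    n_records = nrow(r),
    n_flagged = sum(!is.na(r$data_validity_comment)),
    n_duplicate = sum(r$potential_duplicate),
    n_pchembl = sum(!is.na(r$pchembl_value)),
    pct_flagged = if (nrow(r)) 100 * mean(!is.na(r$data_validity_comment))
      else 0
  )
}

#' Plot a curation report
#'
#' Bar chart of affected-record percentages per workflow step.
#'
#' @param object A `curation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot curation_result
#' @export
autoplot.curation_result <- function(object, ...) {
  d <- object$report
  d$label <- paste0(d$step, ". ", d$name)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$label, .data$step),
    y = .data$percentage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of records affected",
                  title = "Activity curation workflow") +
    ggplot2::theme_minimal()
}

#' Plot flagging precision and recall
#'
#' @param object A `flag_metrics` tibble from [evaluate_flags()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flag_metrics
#' @export
autoplot.flag_metrics <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object)[, c("flag", "precision", "recall")],
                           c("precision", "recall"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$flag, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Flag recovery against ground truth") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
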