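# synthetic messy-literature corpus: a seeded sampling process that
# emulates the error taxonomy of published bioactivity data -- unit
# dialects, log-scale reporting, cross-publication citations (exact or
# rounded), decade unit slips and missing values -- with per-record ground
# truth so every flagging rule can be scored by precision and recall.

# dialects used to render a standard nM value as a published quantity;
# inv_factor multiplies the standard value to give the published value
LINEAR_DIALECTS <- tibble::tribble(
  ~published_units, ~inv_factor,
  "uM",     1e-3,
  "umol/l", 1e-3,
  "mM",     1e-6,
  "M",      1e-9,
  "pM",     1e3,
  "nmol/l", 1
)

#' Parameters for the synthetic corpus generator
#'
#' Defaults describe a plausible medicinal-chemistry literature: true
#' pActivities (the -log10 molar potency of a compound against a target)
#' centred at 6.5 (about 300 nM) with population spread 1.5 log units,
#' inter-assay noise of 0.5 log units, and modest rates of log-scale
#' reporting, exotic unit dialects, citations of earlier papers (half of
#' them re-rounded), decade unit slips and missing values.
#'
#' @param n_compounds,n_targets,n_documents Corpus dimensions; documents
#'   are assigned consecutive publication years.
#' @param measurements_per_pair Integer range `c(min, max)`: measurements
#'   drawn uniformly for each sampled compound-target pair.
#' @param true_pactivity_mean,true_pactivity_sd Normal distribution of
#'   true pActivities (dimensionless, -log10 M scale).
#' @param assay_noise_sd Per-measurement noise, log10 units.
#' @param p_log_reported Probability a clean record is published as a log
#'   type (pIC50/pKi) instead of a concentration.
#' @param p_unit_dialect Probability a concentration record uses a
#'   non-nM dialect (uM, mM, M, pM, ...).
#' @param p_citation Probability an eligible record (one with an
#'   earlier-document record for the same pair) is a citation of the
#'   earliest measurement rather than an independent one.
#' @param p_citation_rounded Probability a citation is re-rounded to 2--3
#'   significant figures.
#' @param p_transcription_error Probability an eligible record is a
#'   citation with a decade unit slip.
#' @param p_missing Probability a clean record loses its published value
#'   (no activity comment either).
#' @param transcription_decades Decades used for injected slips, subset of
#'   `c(3, 6)`.
#' @param fragment_fraction Fraction of compounds that are fragments
#'   (MW < 350).
#' @param seed Integer seed; the full output is reproducible from it.
#' @return A list of class `corpus_params`.
#' @export
corpus_params <- function(n_compounds = 60, n_targets = 8, n_documents = 25,
                          measurements_per_pair = c(1, 3),
                          true_pactivity_mean = 6.5,
                          true_pactivity_sd = 1.5,
                          assay_noise_sd = 0.5,
                          p_log_reported = 0.2,
                          p_unit_dialect = 0.5,
                          p_citation = 0.05,
                          p_citation_rounded = 0.5,
                          p_transcription_error = 0.02,
                          p_missing = 0.01,
                          transcription_decades = c(3, 6),
                          fragment_fraction = 0.1,
                          seed = 1L) {
  p <- as.list(environment())
  probs <- c(p$p_log_reported, p$p_unit_dialect, p$p_citation,
             p$p_citation_rounded, p$p_transcription_error, p$p_missing,
             p$fragment_fraction)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (p$p_citation + p$p_transcription_error > 1) {
    abort("p_citation + p_transcription_error must not exceed 1")
  }
  if (p$true_pactivity_sd < 0 || p$assay_noise_sd < 0) {
    abort("standard deviations must be >= 0")
  }
  if (!all(p$transcription_decades %in% c(3, 6))) {
    abort("transcription_decades must be a subset of c(3, 6)")
  }
  structure(p, class = "corpus_params")
}

# render one standard nM value as published (value, units, type); injected
# records (citations / slips) are always rendered in a linear dialect so
# the standard value survives re-standardisation exactly
render_published <- function(std_value, base_type, log_ok, params) {
  if (log_ok && runif(1) < params$p_log_reported) {
    list(type = paste0("p", base_type),
         value = round_half_up(9 - log10(std_value), 2),
         units = NA_character_, log = TRUE)
  } else if (runif(1) < params$p_unit_dialect) {
    d <- LINEAR_DIALECTS[sample.int(nrow(LINEAR_DIALECTS), 1), ]
    list(type = base_type, value = std_value * d$inv_factor,
         units = d$published_units, log = FALSE)
  } else {
    list(type = base_type, value = std_value, units = "nM", log = FALSE)
  }
}

#' Generate a synthetic messy-literature corpus
#'
#' Draws a true pActivity for every sampled compound-target pair, scatters
#' noisy measurements over documents (publication years are consecutive),
#' renders each as a published record in a random unit dialect or log
#' type, and injects defects: citations of the pair's earliest document
#' (optionally re-rounded to 2--3 significant figures), decade unit slips
#' (x10^3 or x10^6, direction random), and missing values.  Each
#' injected defect is recorded in the ground-truth table.  Records are
#' eligible for citation/slip injection only when an earlier document
#' already reported the pair, and injected records always cite the
#' earliest document, so the "later publication is flagged" rule is
#' checkable.  The intended standard value of every record is chosen so
#' that re-standardising the published fields reproduces it exactly.
#'
#' @param params A [corpus_params()] object.
#' @return A list of class `synthetic_corpus` with elements `records`,
#'   `compounds`, `assays`, `truth` (columns `record_id`, `label`,
#'   `source_record_id`, `standard_value_expected` -- the standard value
#'   the generator intends standardisation to recover) and `params`;
#'   attribute `n_eligible` on `truth` counts the records that entered
#'   the injection draw.
#' @export
generate_corpus <- function(params = corpus_params()) {
  stopifnot(inherits(params, "corpus_params"))
  set.seed(params$seed)

  compounds <- tibble(
    compound_id = new_id("C", seq_len(params$n_compounds), 5),
    molecular_weight = ifelse(
      runif(params$n_compounds) < params$fragment_fraction,
      runif(params$n_compounds, 160, 345),
      runif(params$n_compounds, 355, 600))
  )

  documents <- tibble(
    document_id = new_id("D", seq_len(params$n_documents), 4),
    document_year = 1995L + seq_len(params$n_documents)
  )

  # each target is measured with one endpoint; half Ki, half IC50
  targets <- tibble(
    target_id = new_id("T", seq_len(params$n_targets), 3),
    base_type = rep_len(c("IC50", "Ki"), params$n_targets)
  )

  # one assay per (document, target) pair actually used; created up front
  assay_grid <- tidyr::expand_grid(documents, targets)
  assay_grid$assay_id <- new_id("A", seq_len(nrow(assay_grid)), 6)
  assay_grid$description <- paste0(
    ifelse(assay_grid$base_type == "Ki",
           "Binding affinity to purified recombinant enzyme ",
           "Inhibition of "),
    assay_grid$target_id)

  pairs <- tidyr::expand_grid(
    compound_id = compounds$compound_id,
    target_id = targets$target_id
  )
  pairs$pactivity <- rnorm(nrow(pairs), params$true_pactivity_mean,
                           params$true_pactivity_sd)
  mpp <- params$measurements_per_pair
  pairs$n_meas <- sample.int(mpp[2] - mpp[1] + 1L, nrow(pairs),
                             replace = TRUE) + mpp[1] - 1L

  # expand to measurements and assign documents
  meas <- pairs[rep(seq_len(nrow(pairs)), pairs$n_meas), ]
  n <- nrow(meas)
  meas$document_id <- documents$document_id[
    sample.int(params$n_documents, n, replace = TRUE)]
  meas$document_year <- documents$document_year[
    match(meas$document_id, documents$document_id)]
  meas$record_id <- new_id("R", seq_len(n))
  meas$base_type <- targets$base_type[match(meas$target_id,
                                            targets$target_id)]
  meas$assay_id <- assay_grid$assay_id[
    match(paste(meas$document_id, meas$target_id),
          paste(assay_grid$document_id, assay_grid$target_id))]

  # process measurements of each pair in document order; the earliest
  # document's record anchors citation and slip injections
  meas <- meas[order(meas$compound_id, meas$target_id, meas$document_year,
                     meas$document_id, meas$record_id), ]
  pair_key <- paste(meas$compound_id, meas$target_id)

  published_type <- character(n); published_value <- rep(NA_real_, n)
  published_units <- rep(NA_character_, n); std_intended <- rep(NA_real_, n)
  label <- rep("clean", n); source_id <- rep(NA_character_, n)
  n_eligible <- 0L

  for (key in unique(pair_key)) {
    rows <- which(pair_key == key)
    anchor_std <- NA_real_   # standard value in the pair's earliest document
    anchor_id <- NA_character_
    anchor_year <- NA_integer_
    for (i in rows) {
      eligible <- !is.na(anchor_std) &&
        meas$document_year[i] > anchor_year
      u <- if (eligible) runif(1) else Inf
      if (eligible) n_eligible <- n_eligible + 1L

      if (u < params$p_citation) {
        v <- anchor_std
        if (runif(1) < params$p_citation_rounded) {
          v <- signif_half_up(v, sample(2:3, 1))
        }
        v <- round_standard_value(v)
        rp <- list(type = meas$base_type[i], value = NA, units = NA, log = FALSE)
        d <- LINEAR_DIALECTS[sample.int(nrow(LINEAR_DIALECTS), 1), ]
        rp$value <- v * d$inv_factor; rp$units <- d$published_units
        std_intended[i] <- v
        label[i] <- "citation_duplicate"; source_id[i] <- anchor_id
      } else if (u < params$p_citation + params$p_transcription_error) {
        k <- params$transcription_decades[
          sample.int(length(params$transcription_decades), 1)]
        v <- round_standard_value(anchor_std * 10^(k * sample(c(-1, 1), 1)))
        d <- LINEAR_DIALECTS[sample.int(nrow(LINEAR_DIALECTS), 1), ]
        rp <- list(type = meas$base_type[i], value = v * d$inv_factor,
                   units = d$published_units, log = FALSE)
        std_intended[i] <- v
        label[i] <- "transcription_error"; source_id[i] <- anchor_id
      } else {
        raw_nm <- 10^(9 - (meas$pactivity[i] +
                             rnorm(1, 0, params$assay_noise_sd)))
        rp <- render_published(round_standard_value(raw_nm),
                               meas$base_type[i], log_ok = TRUE, params)
        if (rp$log) {
          # published log value defines the intended standard value
          std_intended[i] <- round_standard_value(10^(9 - rp$value))
        } else {
          std_intended[i] <- round_standard_value(raw_nm)
        }
        if (runif(1) < params$p_missing) {
          rp$value <- NA_real_; rp$units <- NA_character_
          std_intended[i] <- NA_real_
          label[i] <- "missing"
        }
      }
      published_type[i] <- rp$type
      published_value[i] <- rp$value
      published_units[i] <- rp$units
      if (is.na(anchor_std) && label[i] != "missing" &&
          !is.na(std_intended[i])) {
        anchor_std <- std_intended[i]
        anchor_id <- meas$record_id[i]
        anchor_year <- meas$document_year[i]
      }
    }
  }

  records <- activity_records(tibble(
    record_id = meas$record_id,
    document_id = meas$document_id,
    document_year = meas$document_year,
    assay_id = meas$assay_id,
    compound_id = meas$compound_id,
    published_type = published_type,
    published_relation = "=",
    published_value = published_value,
    published_units = published_units
  ))
  records <- records[order(records$record_id), ]

  truth <- tibble(record_id = meas$record_id, label = label,
                  source_record_id = source_id,
                  standard_value_expected = std_intended)
  truth <- truth[order(truth$record_id), ]
  attr(truth, "n_eligible") <- n_eligible

  assays <- assay_records(assay_grid[
    assay_grid$assay_id %in% records$assay_id,
    c("assay_id", "document_id", "description", "target_id")])

  structure(list(records = records, compounds = compounds, assays = assays,
                 truth = truth, params = params),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus>", nrow(x$records), "records,",
      nrow(x$compounds), "compounds,", nrow(x$assays), "assays\n")
  print(table(x$truth$label))
  invisible(x)
}

#' Score pipeline flags against ground truth
#'
#' Builds a confusion matrix per flag class -- missing-data comments,
#' duplicate flags and transcription-error comments -- against the
#' generator's injected labels, and reports precision and recall (NA when
#' the denominator is zero).
#'
#' @param records Curated activity tibble (pipeline output).
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @return A tibble of class `flag_metrics`: `flag`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`.
#' @export
evaluate_flags <- function(records, truth) {
  r <- activity_records(records)
  if (!setequal(r$record_id, truth$record_id)) {
    abort("records and truth must cover the same record_ids")
  }
  truth <- truth[match(r$record_id, truth$record_id), ]

  score <- function(flag, predicted, actual) {
    tp <- sum(predicted & actual); fp <- sum(predicted & !actual)
    fn <- sum(!predicted & actual)
    tibble(flag = flag, tp = tp, fp = fp, fn = fn,
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }

  cmt <- r$data_validity_comment
  out <- bind_rows(
    score("missing", chr_in(cmt, "Potential missing data"),
          truth$label == "missing"),
    score("potential_duplicate", r$potential_duplicate,
          truth$label == "citation_duplicate"),
    score("transcription_error", chr_in(cmt, "Potential transcription error"),
          truth$label == "transcription_error")
  )
  class(out) <- c("flag_metrics", class(out))
  out
}
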