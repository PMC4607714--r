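cfg <- curation_config()

test_that("published type spellings collapse onto canonical standard types", {
  expect_equal(normalize_type("Half life", cfg), "T1/2")
  expect_equal(normalize_type("t(1/2)", cfg), "T1/2")
  expect_equal(normalize_type("half-life", cfg), "T1/2")
  expect_equal(normalize_type("IC50", cfg), "IC50")
  expect_equal(normalize_type("  ic 50 ", cfg), "IC50")
  # unknown types pass through trimmed, not invented
  expect_equal(normalize_type(" Strange endpoint ", cfg), "Strange endpoint")
})

test_that("unit dialects convert within their dimension class", {
  out <- convert_units(c(1, 5, 1), c("=", ">", "="),
                       c("uM", "ng/ml", "ug h/ml"),
                       c("IC50", "IC50", "AUC"), cfg)
  expect_true(all(out$ok))
  expect_equal(out$standard_value, c(1000, 0.005, 1000))
  expect_equal(out$standard_units, c("nM", "ug.mL-1", "ng.h.mL-1"))
  expect_equal(out$standard_relation, c("=", ">", "="))
})

test_that("separator and case variants of a unit hit the same entry", {
  for (u in c("uM", "um", "µM", "umol/l", "umol.l-1", "uMOL / L")) {
    out <- convert_units(2, "=", u, "IC50", cfg)
    expect_true(out$ok, info = u)
    expect_equal(out$standard_value, 2000, info = u)
  }
})

test_that("unknown units and unphysical concentrations fail conversion softly", {
  out <- convert_units(c(50, -3), c("=", "="), c("%", "uM"),
                       c("IC50", "IC50"), cfg)
  expect_false(any(out$ok))
  # value and units pass through for the downstream unit flagger
  expect_equal(out$standard_value, c(50, -3))
  expect_equal(out$standard_units, c("%", "uM"))
})

test_that("negative-log types unlog to nM and flip censored relations", {
  out <- unlog_value(c("pKi", "pKi", "logIC50"), c(9, 6, -7),
                     c("=", ">", "="), cfg)
  expect_equal(out$standard_type, c("Ki", "Ki", "IC50"))
  expect_equal(out$standard_value, c(1, 1000, 100), tolerance = 1e-12)
  expect_equal(out$standard_relation, c("=", "<", "="))
  expect_equal(out$standard_units, rep("nM", 3))
  # unknown log type passes through untouched
  pass <- unlog_value("pFoo", 5, "=", cfg)
  expect_false(pass$ok)
  expect_equal(pass$standard_value, 5)
})

test_that("relation flipping is an involution", {
  rels <- c("<", "<=", "=", ">=", ">", "~")
  flip <- sarclean:::flip_relation
  expect_equal(flip(flip(rels)), rels)
  expect_equal(flip(c("<", ">=")), c(">", "<="))
})

test_that("the two-tier rounding rule matches its worked examples", {
  expect_equal(round_standard_value(1.23456), 1.23)
  expect_equal(round_standard_value(123.456), 123.46)
  expect_equal(round_standard_value(0.0123456), 0.0123)
  expect_equal(round_standard_value(NA_real_), NA_real_)
  expect_equal(round_standard_value(0), 0)
})

test_that("rounding is half-up and idempotent", {
  # decimal halves go up in both tiers
  expect_equal(round_standard_value(1.005), 1.01)
  expect_equal(round_standard_value(2.345), 2.35)
  expect_equal(round_standard_value(123.455), 123.46)
  expect_equal(round_standard_value(99.995), 100)
  x <- 10^runif(200, -4, 7)
  r1 <- round_standard_value(x)
  expect_equal(round_standard_value(r1), r1)
})

test_that("standardisation composes normalisation, unlogging, conversion, rounding", {
  r <- make_records(
    list(published_type = "pKi", published_value = 7.5),
    list(published_type = "IC50", published_value = 2,
         published_units = "uM"),
    list(published_type = "IC50")
  )
  out <- standardize_activities(r, cfg)
  expect_equal(out$standard_type[1], "Ki")
  # 10^(-7.5) M = 31.6227... nM, >= 10 so rounded to the second decimal
  expect_equal(out$standard_value[1], 31.62)
  expect_equal(out$standard_units[1], "nM")
  expect_equal(out$standard_value[2], 2000)
  # no published value: no standard fields at all
  expect_true(all(is.na(out[3, c("standard_type", "standard_value",
                                 "standard_units")])))
  expect_equal(attr(out, "n_log_converted"), 1L)
})

test_that("standardisation is idempotent and never touches published fields", {
  corpus <- generate_corpus(corpus_params(n_compounds = 15, n_targets = 3,
                                          n_documents = 8, seed = 11))
  pub_cols <- c("record_id", "document_id", "assay_id", "compound_id",
                "published_type", "published_relation", "published_value",
                "published_units", "activity_comment")
  s1 <- standardize_activities(corpus$records, cfg)
  s2 <- standardize_activities(s1, cfg)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_equal(corpus$records[, pub_cols], s1[, pub_cols],
               ignore_attr = TRUE)
})

test_that("conversions round-trip back to the published unit within rounding", {
  conv <- cfg$unit_conversions
  for (i in seq_len(nrow(conv))) {
    x <- 3.21
    std <- x * conv$factor[i]
    back <- std / conv$factor[i]
    expect_equal(back, x, tolerance = 1e-9, info = conv$pattern[i])
  }
})

test_that("pChEMBL recovers a published pKi through the full standardisation", {
  pki <- round(seq(1.01, 10.99, length.out = 60), 2)
  r <- make_records()[0, ]
  r <- activity_records(tibble::tibble(
    record_id = paste0("p", seq_along(pki)),
    document_id = "d1", assay_id = "a1",
    compound_id = paste0("c", seq_along(pki)),
    published_type = "pKi", published_relation = "=",
    published_value = pki, published_units = NA_character_
  ))
  out <- add_pchembl(standardize_activities(r, cfg), cfg)
  expect_true(all(abs(out$pchembl_value - pki) <= 0.005 + 1e-12))
})
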