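cfg <- curation_config()

test_that("missing-data flag requires both value and comment to be absent", {
  r <- make_records(
    list(),                                       # no value, no comment
    list(activity_comment = "Not active"),        # comment excuses
    list(published_value = 50, published_units = "nM")
  )
  out <- flag_missing(r)
  expect_equal(out$data_validity_comment,
               c("Potential missing data", NA, NA))
})

test_that("non-standard, unknown or null units are flagged per type", {
  r <- make_records(
    list(published_value = 5, standard_type = "IC50",
         standard_value = 5, standard_units = "nM"),
    list(published_value = 5, standard_type = "IC50",
         standard_value = 5, standard_units = "%"),
    list(published_value = 5, standard_type = "IC50", standard_value = 5),
    list(published_value = 5, standard_type = "UnpolicedType",
         standard_value = 5, standard_units = "furlongs")
  )
  out <- flag_nonstandard_units(r, cfg)
  expect_equal(out$data_validity_comment,
               c(NA, "Non standard unit for type",
                 "Non standard unit for type", NA))
})

test_that("out-of-range flagging uses the inclusive 0.01 nM - 100 uM window", {
  vals <- c(0.005, 0.01, 50, 1e5, 1.1e5)
  r <- activity_records(tibble::tibble(
    record_id = paste0("r", seq_along(vals)),
    document_id = "d1", assay_id = "a1", compound_id = "c1",
    published_type = "IC50", published_relation = "=",
    published_value = vals, published_units = "nM",
    standard_type = "IC50", standard_relation = "=",
    standard_value = vals, standard_units = "nM"
  ))
  out <- flag_out_of_range(r, one_compound(mw = 450), cfg)
  expect_equal(!is.na(out$data_validity_comment),
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$data_validity_comment[1], "Outside typical range")
})

test_that("fragments get a relaxed upper bound but no relaxed lower bound", {
  r <- make_records(
    list(published_value = 5e5, published_units = "nM",
         standard_type = "Ki", standard_relation = "=",
         standard_value = 5e5, standard_units = "nM"),
    list(published_value = 0.005, published_units = "nM",
         standard_type = "Ki", standard_relation = "=",
         standard_value = 0.005, standard_units = "nM")
  )
  fragment <- one_compound(mw = 300)
  heavy <- one_compound(mw = 450)
  # 5e5 <= 1e5 * 100: inside the relaxed window for a fragment
  expect_true(is.na(flag_out_of_range(r, fragment, cfg)$data_validity_comment[1]))
  expect_false(is.na(flag_out_of_range(r, heavy, cfg)$data_validity_comment[1]))
  # the lower bound is not relaxed
  expect_false(is.na(flag_out_of_range(r, fragment, cfg)$data_validity_comment[2]))
})

test_that("fragment relaxation only ever unflags relative to the strict rule", {
  set.seed(31)
  vals <- 10^runif(300, -4, 9)
  r <- activity_records(tibble::tibble(
    record_id = paste0("r", seq_along(vals)),
    document_id = "d1", assay_id = "a1", compound_id = "c1",
    published_type = "IC50", published_relation = "=",
    published_value = vals, published_units = "nM",
    standard_type = "IC50", standard_relation = "=",
    standard_value = vals, standard_units = "nM"
  ))
  strict <- !is.na(flag_out_of_range(r, one_compound(mw = 500),
                                     cfg)$data_validity_comment)
  relaxed <- !is.na(flag_out_of_range(r, one_compound(mw = 200),
                                      cfg)$data_validity_comment)
  expect_true(all(relaxed <= strict))
})

test_that("range flagging is monotone: interior points are never flagged", {
  vals <- 10^seq(log10(0.01), log10(1e5), length.out = 50)
  r <- activity_records(tibble::tibble(
    record_id = paste0("r", seq_along(vals)),
    document_id = "d1", assay_id = "a1", compound_id = "c1",
    published_type = "Ki", published_relation = "=",
    published_value = vals, published_units = "nM",
    standard_type = "Ki", standard_relation = "=",
    standard_value = vals, standard_units = "nM"
  ))
  out <- flag_out_of_range(r, one_compound(mw = 450), cfg)
  expect_true(all(is.na(out$data_validity_comment)))
})

test_that("earlier flags take precedence and corpus size is conserved", {
  r <- make_records(
    list(standard_type = "IC50")   # missing value AND missing units
  )
  out <- flag_nonstandard_units(flag_missing(r), cfg)
  expect_equal(out$data_validity_comment, "Potential missing data")
  expect_equal(nrow(out), nrow(r))

  # a record with a (type, unit) pair absent from the range table: no flag
  r2 <- make_records(
    list(published_value = 1e9, published_units = "hr",
         standard_type = "T1/2", standard_relation = "=",
         standard_value = 1e9, standard_units = "hr")
  )
  expect_true(is.na(flag_out_of_range(r2, one_compound(),
                                      cfg)$data_validity_comment))
})
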