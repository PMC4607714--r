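cfg <- curation_config()

std_rec <- function(id, doc, year, value, compound = "c1", assay = "a1",
                    type = "Ki", units = "nM") {
  tibble::tibble(
    record_id = id, document_id = doc, document_year = year,
    assay_id = assay, compound_id = compound,
    published_type = type, published_relation = "=",
    published_value = value, published_units = units,
    standard_type = type, standard_relation = "=",
    standard_value = value, standard_units = units
  )
}

test_that("grouping keys on compound, target, standard type and units", {
  r <- activity_records(dplyr::bind_rows(
    std_rec("r1", "d1", 2001, 50), std_rec("r2", "d2", 2002, 51),
    std_rec("r3", "d3", 2003, 52),
    std_rec("r4", "d1", 2001, 5, units = "ug.mL-1"),
    std_rec("r5", "d1", 2001, NA)   # no standard value: skipped
  ))
  g <- build_match_groups(r, one_assay())
  expect_equal(dplyr::n_distinct(g$group_id), 2)
  expect_equal(nrow(g), 4)
  expect_equal(attr(g, "n_skipped"), 1L)

  empty <- build_match_groups(r[0, ], one_assay())
  expect_equal(nrow(empty), 0)
})

test_that("a rounded cross-publication citation flags the later paper only", {
  m <- make_members(c(53.7, 54), c("dA", "dB"), c(2001, 2003))
  expect_equal(detect_duplicates(m), "m2")

  # same-document repeats (racemate and stereoisomers) are legitimate
  same <- make_members(c(50, 50), c("dA", "dA"), c(2001, 2001))
  expect_equal(detect_duplicates(same), character())

  # unrelated values never match
  far <- make_members(c(50, 70), c("dA", "dB"), c(2001, 2003))
  expect_equal(detect_duplicates(far), character())
})

test_that("the earliest document of a matched cluster is never flagged", {
  set.seed(91)
  for (i in 1:25) {
    m <- random_group(sample(3:12, 1))
    flagged <- detect_duplicates(m)
    if (!length(flagged)) next
    rnk <- sarclean:::doc_rank(m$document_id, m$document_year)
    earliest_overall <- m$record_id[which.min(rnk)]
    expect_false(earliest_overall %in% flagged)
  }
})

test_that("decade offsets of 3 and 6 orders flag the later publication", {
  m3 <- make_members(c(50, 5e4), c("dA", "dB"), c(2001, 2003))
  expect_equal(detect_transcription_errors(m3), "m2")

  m6 <- make_members(c(2.5, 2.5e6), c("dA", "dB"), c(2001, 2003))
  expect_equal(detect_transcription_errors(m6), "m2")

  # 2 orders is not a unit slip
  m2 <- make_members(c(50, 5e3), c("dA", "dB"), c(2001, 2003))
  expect_equal(detect_transcription_errors(m2), character())

  # cross-document is required even at an exact decade offset
  same_doc <- make_members(c(50, 5e4), c("dA", "dA"), c(2001, 2001))
  expect_equal(detect_transcription_errors(same_doc), character())

  # the later record is the flagged one regardless of which is larger
  m_dn <- make_members(c(5e4, 50), c("dA", "dB"), c(2001, 2003))
  expect_equal(detect_transcription_errors(m_dn), "m2")
})

test_that("a re-rounded decade slip of a many-digit value still matches", {
  # 195659.34 / 1000 re-rounds to 195.66 under the standard rounding rule
  m <- make_members(c(195659.34, 195.66), c("dA", "dB"), c(2001, 2003))
  expect_equal(detect_transcription_errors(m), "m2")
})

test_that("flag write-back conserves records and separates the two flags", {
  r <- activity_records(dplyr::bind_rows(
    std_rec("orig", "d1", 2001, 53.7),
    std_rec("cite", "d2", 2003, 54),
    std_rec("slip", "d3", 2004, 53700),
    std_rec("indep", "d4", 2005, 61.2)
  ))
  out <- apply_redundancy_flags(r, one_assay(), cfg)
  expect_equal(nrow(out), 4)
  expect_equal(out$record_id[out$potential_duplicate], "cite")
  expect_equal(
    out$record_id[!is.na(out$data_validity_comment) &
                    out$data_validity_comment == "Potential transcription error"],
    "slip")
  expect_true(is.na(out$data_validity_comment[out$record_id == "orig"]))

  # no repeated pair anywhere: zero flags
  lonely <- activity_records(dplyr::bind_rows(
    std_rec("x1", "d1", 2001, 50, compound = "cA"),
    std_rec("x2", "d2", 2002, 50, compound = "cB")
  ))
  out2 <- apply_redundancy_flags(lonely, one_assay(), cfg)
  expect_false(any(out2$potential_duplicate))
  expect_true(all(is.na(out2$data_validity_comment)))
})

test_that("detection equals the brute-force pairwise oracle on random groups", {
  set.seed(17)
  for (i in 1:120) {
    m <- random_group(sample(2:20, 1), group_tag = i)
    expect_setequal(detect_duplicates(m), oracle_duplicates(m))
    expect_setequal(detect_transcription_errors(m), oracle_transcription(m))
  }
})

test_that("output is invariant under permutation of record order", {
  set.seed(29)
  for (i in 1:20) {
    m <- random_group(sample(3:15, 1))
    p <- m[sample(nrow(m)), ]
    expect_setequal(detect_duplicates(m), detect_duplicates(p))
    expect_setequal(detect_transcription_errors(m),
                    detect_transcription_errors(p))
  }
})

test_that("adding a record never removes an already matched pair", {
  vm <- sarclean:::values_match
  set.seed(53)
  for (i in 1:20) {
    m <- random_group(sample(3:12, 1))
    extra <- random_group(1)
    extra$record_id <- "extra"
    grown <- dplyr::bind_rows(m, extra)
    pairs_of <- function(g) {
      idx <- which(upper.tri(diag(nrow(g))), arr.ind = TRUE)
      keep <- g$document_id[idx[, 1]] != g$document_id[idx[, 2]] &
        vm(g$standard_value[idx[, 1]], g$standard_value[idx[, 2]])
      paste(pmin(g$record_id[idx[, 1]], g$record_id[idx[, 2]])[keep],
            pmax(g$record_id[idx[, 1]], g$record_id[idx[, 2]])[keep])
    }
    expect_true(all(pairs_of(m) %in% pairs_of(grown)))
  }
})
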