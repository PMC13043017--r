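# Rubric validation and aggregation rules.

test_that("existence = 0 with positive content scores is valid; ranges are not", {
  rec <- make_expert_records(raters = 1, docs = "docA", versions = "original")
  rec$existence[1] <- 0
  rec$specificity[1] <- 2
  rec$operability[1] <- 1
  expect_equal(nrow(validate_expert_scores(rec)), 0)

  rec$specificity[2] <- 3
  report <- validate_expert_scores(rec)
  expect_equal(report$type, "range")
  expect_equal(report$indicator_id, rec$indicator_id[2])
})

test_that("aggregation hits the documented bounds and averaging order", {
  # one rater, everything at maximum: subtotals 20/40/40, total 100
  top <- aggregate_expert(make_expert_records(raters = 1, docs = "docA",
                                              versions = "original"))
  expect_equal(top$existence, 20)
  expect_equal(top$specificity, 40)
  expect_equal(top$operability, 40)
  expect_equal(top$total, 100)

  zero <- aggregate_expert(make_expert_records(
    raters = 1, docs = "docA", versions = "original",
    existence = 0, specificity = 0, operability = 0
  ))
  expect_equal(zero$total, 0)

  # two raters with document totals 40 and 50 average to 45
  rec <- make_expert_records(raters = 2, docs = "docA", versions = "original",
                             existence = 0, specificity = 1, operability = 1)
  rec$specificity[rec$rater_id == "expert02"] <- 1
  rec$operability[rec$rater_id == "expert02"] <- 1.0
  rec$existence[rec$rater_id == "expert02"] <- 0
  # rater 1: 0/20/20 -> 40; make rater 2 sum to 50
  rec$existence[rec$rater_id == "expert02" & rec$indicator_id <= 10] <- 1
  agg <- aggregate_expert(rec)
  expect_equal(agg$total, 45)

  # per-rater aggregates retain the unaveraged totals
  by_rater <- aggregate_expert(rec, by_rater = TRUE)
  expect_setequal(by_rater$total, c(40, 50))
})

test_that("comprehension aggregation: dimension means, totals, bounds", {
  top <- aggregate_comprehension(make_reader_records(
    raters = 1, docs = "docA", versions = "original", score = 5
  ))
  expect_equal(top$total, 30)
  expect_equal(top$dimension_means, 5)

  low <- aggregate_comprehension(make_reader_records(
    raters = 1, docs = "docA", versions = "original", score = 1
  ))
  expect_equal(low$total, 6)
  expect_equal(low$dimension_means, 1)

  rec <- make_reader_records(raters = 2, docs = "docA", versions = "original", score = 3)
  rec$clarity[rec$rater_id == "reader02"] <- 4
  agg <- aggregate_comprehension(rec)
  expect_equal(agg$clarity, 3.5)
  expect_equal(agg$total, 5 * 3 + 3.5)
  expect_equal(agg$dimension_means, agg$total / 6)
})

test_that("aggregates stay within bounds on random valid inputs", {
  withr::local_seed(42)
  for (rep in 1:5) {
    rec <- make_expert_records(raters = 3)
    n <- nrow(rec)
    rec$existence <- sample(0:1, n, replace = TRUE)
    rec$specificity <- sample(0:2, n, replace = TRUE)
    rec$operability <- sample(0:2, n, replace = TRUE)
    agg <- aggregate_expert(rec)
    expect_true(all(agg$total >= 0 & agg$total <= 100))
    expect_true(all(abs(agg$total - (agg$existence + agg$specificity + agg$operability)) < 1e-12))

    rdr <- make_reader_records(raters = 3)
    for (dim in c("comprehensibility", "clarity", "trustworthiness",
                  "friendliness", "professionalism", "acceptability")) {
      rdr[[dim]] <- sample(1:5, nrow(rdr), replace = TRUE)
    }
    cagg <- aggregate_comprehension(rdr)
    expect_true(all(cagg$total >= 6 & cagg$total <= 30))
    expect_equal(cagg$dimension_means, cagg$total / 6)
  }
})

test_that("rater and record order never change the aggregates", {
  withr::local_seed(7)
  rec <- make_expert_records(raters = 3)
  rec$specificity <- sample(0:2, nrow(rec), replace = TRUE)
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(
    dplyr::arrange(aggregate_expert(rec), doc_id, version),
    dplyr::arrange(aggregate_expert(shuffled), doc_id, version)
  )
  expect_equal(
    dplyr::arrange(indicator_profile(rec), indicator_id, version),
    dplyr::arrange(indicator_profile(shuffled), indicator_id, version)
  )
})

test_that("indicator profile is consistent with the aggregates", {
  withr::local_seed(13)
  rec <- make_expert_records(raters = 2, docs = "docA", versions = "original")
  rec$existence <- sample(0:1, nrow(rec), replace = TRUE)
  rec$specificity <- sample(0:2, nrow(rec), replace = TRUE)
  rec$operability <- sample(0:2, nrow(rec), replace = TRUE)

  prof <- indicator_profile(rec)
  expect_equal(nrow(prof), 20)
  agg <- aggregate_expert(rec)
  # summing the per-indicator means over indicators reproduces the subtotals
  expect_equal(sum(prof$existence), agg$existence)
  expect_equal(sum(prof$specificity), agg$specificity)
  expect_equal(sum(prof$operability), agg$operability)
  expect_equal(sum(prof$total), agg$total)

  # single rater, single doc: the profile is the raw scores
  one <- rec[rec$rater_id == "expert01", ]
  p1 <- dplyr::arrange(indicator_profile(one), indicator_id)
  expect_equal(p1$existence, dplyr::arrange(one, indicator_id)$existence)
})

test_that("missing cells block aggregation unless partial data is allowed", {
  rec <- make_expert_records(raters = 2, docs = c("docA", "docB"),
                             versions = "original")
  gap <- !(rec$rater_id == "expert01" & rec$doc_id == "docA" & rec$indicator_id == 7)
  expect_error(aggregate_expert(rec[gap, ]), class = "icfeval_validation_error")

  agg <- aggregate_expert(rec[gap, ], allow_partial = TRUE, by_rater = TRUE)
  # the incomplete rater is dropped for docA only, never rescaled
  expect_equal(nrow(agg), 3)
  expect_false(any(agg$rater_id == "expert01" & agg$doc_id == "docA"))
  expect_true(all(agg$total == 100))
})

test_that("the shipped codebook defines the 20 indicators", {
  defs <- icf_indicators()
  expect_equal(nrow(defs), 20)
  expect_equal(defs$indicator_id, 1:20)
  expect_false(any(duplicated(defs$name)))
  expect_true("exceptions to confidentiality" %in% defs$name)
})
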