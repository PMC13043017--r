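# Reading and writing corpora, lexicons and score tables.

test_that("corpus round-trips through manifest and files, order-independently", {
  docs <- tibble::tibble(
    doc_id = rep(c("docA", "docB"), each = 3),
    version = rep(c("original", "chatgpt5", "grok4"), 2),
    text = paste0("sentence ", 1:6, "。")
  )
  dir <- withr::local_tempdir()
  manifest <- write_corpus(docs, dir)
  got <- read_corpus(manifest, complete = TRUE)
  expect_equal(nrow(got), 6)
  expect_equal(
    dplyr::arrange(got, doc_id, version),
    dplyr::arrange(docs, doc_id, version)
  )

  # permuting manifest rows yields an equal corpus
  m <- read.csv(manifest, stringsAsFactors = FALSE)
  write.csv(m[rev(seq_len(nrow(m))), ], manifest, row.names = FALSE)
  got2 <- read_corpus(manifest)
  expect_equal(
    dplyr::arrange(got2, doc_id, version),
    dplyr::arrange(got, doc_id, version)
  )
})

test_that("manifest validation is total: duplicates, missing files, empty text", {
  docs <- tibble::tibble(
    doc_id = "docA", version = c("original", "chatgpt5"),
    text = c("one.", "two.")
  )
  dir <- withr::local_tempdir()
  manifest <- write_corpus(docs, dir)

  m <- read.csv(manifest, stringsAsFactors = FALSE)
  write.csv(rbind(m, m[1, ]), manifest, row.names = FALSE)
  expect_error(read_corpus(manifest), class = "icfeval_validation_error")

  m$path[2] <- "does_not_exist.txt"
  write.csv(m, manifest, row.names = FALSE)
  expect_error(read_corpus(manifest), "does_not_exist",
               class = "icfeval_io_error")

  # empty document text
  writeLines("   ", file.path(dir, m$path[1]))
  m$path[2] <- m$path[1]
  m$version[2] <- "chatgpt5"
  write.csv(m, manifest, row.names = FALSE)
  expect_error(read_corpus(manifest), class = "icfeval_validation_error")

  # incomplete corpus under the complete flag
  manifest2 <- write_corpus(docs[1, ], withr::local_tempdir())
  expect_error(
    read_corpus(manifest2, versions = c("original", "chatgpt5"), complete = TRUE),
    class = "icfeval_validation_error"
  )
})

test_that("a 33-document, 3-version corpus yields 99 evaluation units", {
  gen <- generate_corpus(synth_config(n_docs = 33), seed = 11)
  dir <- withr::local_tempdir()
  manifest <- write_corpus(gen$corpus, dir)
  got <- read_corpus(manifest, complete = TRUE)
  expect_equal(nrow(got), 99)
  expect_equal(
    dplyr::arrange(got, doc_id, version),
    dplyr::arrange(gen$corpus, doc_id, version)
  )
})

test_that("lexicon files: comments and duplicates handled, overlap rejected", {
  dir <- withr::local_tempdir()
  polite <- file.path(dir, "polite.txt")
  harsh <- file.path(dir, "harsh.txt")
  writeLines(c("# polite terms", "请", "", "感谢", "请"), polite)
  writeLines(c("必须", "禁止"), harsh)
  lex <- read_lexicon(polite, harsh)
  expect_length(lex$polite, 2) # duplicate collapsed, comment skipped
  expect_length(lex$harsh, 2)

  writeLines(c("必须", "请"), harsh)
  expect_error(read_lexicon(polite, harsh), "请",
               class = "icfeval_validation_error")
  writeLines(character(0), harsh)
  expect_error(read_lexicon(polite, harsh), class = "icfeval_validation_error")
})

test_that("score tables validate ranges and round-trip through CSV", {
  records <- make_expert_records(raters = 1, docs = "docA", versions = "original")
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_table(records, path)
  got <- read_score_table(path, "expert_rubric")
  expect_equal(nrow(got), 20)
  expect_equal(
    dplyr::arrange(got, indicator_id)[names(records)],
    dplyr::arrange(records, indicator_id),
    ignore_attr = TRUE
  )

  bad <- records
  bad$existence[3] <- 2
  write_score_table(bad, path)
  expect_error(read_score_table(path, "expert_rubric"),
               class = "icfeval_validation_error")

  readers <- make_reader_records(raters = 1, docs = "docA", versions = "original")
  readers$comprehensibility[1] <- 6 # Likert maximum is 5
  write_score_table(readers, path)
  expect_error(read_score_table(path, "reader_scale"),
               class = "icfeval_validation_error")
})

test_that("completeness check names the missing cell", {
  records <- make_expert_records(raters = 2, docs = "docA", versions = "original")
  gap <- !(records$rater_id == "expert01" & records$indicator_id == 7)
  report <- validate_expert_scores(records[gap, ])
  miss <- report[report$type == "incomplete", ]
  expect_equal(nrow(miss), 1)
  expect_equal(miss$rater_id, "expert01")
  expect_equal(miss$doc_id, "docA")
  expect_equal(miss$indicator_id, 7L)
})

test_that("reports round-trip through JSON with exact numeric values", {
  report <- run_pipeline(list(
    synthetic = list(n_docs = 4),
    seed = 3,
    stages = list(lmm = FALSE) # keep the fixture fast
  ))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(report, path)
  got <- read_report(path)
  expect_equal(got$metrics$table$lee_yang_index, report$metrics$table$lee_yang_index)
  expect_equal(got$metrics$comparisons$p_fdr, report$metrics$comparisons$p_fdr)
  expect_equal(got$quality$aggregates$total, report$quality$aggregates$total)
  expect_equal(got$comprehension$icc$value, report$comprehension$icc$value)

  # one comparison row per outcome and version pair
  expect_equal(nrow(report$metrics$comparisons), 8 * 3)

  # an empty bundle still writes a valid report
  empty <- run_pipeline(list(stages = list(
    metrics = FALSE, rubric = FALSE, comprehension = FALSE,
    wilcoxon = FALSE, icc = FALSE, lmm = FALSE
  )))
  path2 <- withr::local_tempfile(fileext = ".json")
  write_report(empty, path2)
  expect_true(file.exists(path2))
  expect_null(read_report(path2)$metrics)
})
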