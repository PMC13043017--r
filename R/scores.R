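# Long-format rater score tables: reading, validation, completeness.

expert_cols <- c("rater_id", "doc_id", "version", "indicator_id",
                 "existence", "specificity", "operability")
reader_dims <- c("comprehensibility", "clarity", "trustworthiness",
                 "friendliness", "professionalism", "acceptability")
reader_cols <- c("rater_id", "doc_id", "version", reader_dims)

expert_bounds <- list(existence = c(0, 1), specificity = c(0, 2), operability = c(0, 2))

#' Read a long-format rater score table
#'
#' Two schemas are supported. `expert_rubric`: one row per
#' (rater, document, version, indicator) with the three bounded dimensions
#' `existence` (0–1), `specificity` (0–2) and `operability` (0–2). An
#' indicator mentioned only inside another section scores `existence = 0`
#' while specificity and operability are still assessed, so `existence = 0`
#' with positive content scores is valid. `reader_scale`: one row per
#' (rater, document, version) with six 1–5 Likert columns
#' (`comprehensibility`, `clarity`, `trustworthiness`, `friendliness`,
#' `professionalism`, `acceptability`).
#'
#' @param path Delimited text file with header (comma or tab, sniffed).
#' @param schema `"expert_rubric"` or `"reader_scale"`.
#' @return A tibble with attribute `schema`; every value cell validated
#'   against the schema bounds and duplicate key rows rejected.
#' @export
read_score_table <- function(path, schema = c("expert_rubric", "reader_scale")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort_io(sprintf("score table not found: %s", path))
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  as_score_table(tibble::as_tibble(df), schema)
}

#' Validate and tag a score tibble
#'
#' Applies the same schema validation as [read_score_table()] to an in-memory
#' tibble; errors describe the offending row coordinates.
#'
#' @param df A tibble/data.frame.
#' @param schema `"expert_rubric"` or `"reader_scale"`.
#' @return The validated tibble with attribute `schema`.
#' @export
as_score_table <- function(df, schema = c("expert_rubric", "reader_scale")) {
  schema <- match.arg(schema)
  report <- if (schema == "expert_rubric") {
    validate_expert_scores(df, check_complete = FALSE)
  } else {
    validate_reader_scores(df, check_complete = FALSE)
  }
  stop_on_violations(report)
  df <- tibble::as_tibble(df)
  attr(df, "schema") <- schema
  df
}

#' Validate expert rubric records
#'
#' Report-style validation: returns every violation found rather than failing
#' on the first. Checks schema columns, integer ranges (existence in 0–1,
#' specificity and operability in 0–2), duplicate (rater, doc, version,
#' indicator) keys, and — when `check_complete` — that every observed rater x
#' document x version cell carries all 20 indicators. `existence = 0`
#' combined with positive specificity or operability is explicitly valid.
#'
#' @param records Expert rubric tibble (see [read_score_table()]).
#' @param check_complete Check the full rater x doc x version x indicator grid.
#' @param indicators Integer vector of expected indicator ids.
#' @return A tibble of violations (zero rows when valid) with columns `type`,
#'   `rater_id`, `doc_id`, `version`, `indicator_id`, `message`.
#' @export
validate_expert_scores <- function(records, check_complete = TRUE,
                                   indicators = 1:20) {
  assert_columns(records, expert_cols, "expert rubric table")
  v <- list()
  for (dim in names(expert_bounds)) {
    b <- expert_bounds[[dim]]
    x <- records[[dim]]
    bad <- which(is.na(x) | x != floor(x) | x < b[1] | x > b[2])
    if (length(bad) > 0) {
      v[[length(v) + 1L]] <- tibble::tibble(
        type = "range",
        rater_id = as.character(records$rater_id[bad]),
        doc_id = as.character(records$doc_id[bad]),
        version = as.character(records$version[bad]),
        indicator_id = as.integer(records$indicator_id[bad]),
        message = sprintf("%s=%s outside {%d..%d}", dim, x[bad], b[1], b[2])
      )
    }
  }
  bad_ind <- which(!records$indicator_id %in% indicators)
  if (length(bad_ind) > 0) {
    v[[length(v) + 1L]] <- violation_rows("unknown_indicator", records, bad_ind,
                                          "indicator_id outside the codebook")
  }
  key <- paste(records$rater_id, records$doc_id, records$version,
               records$indicator_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    v[[length(v) + 1L]] <- violation_rows("duplicate", records, dup,
                                          "duplicate (rater, doc, version, indicator) row")
  }
  if (check_complete) {
    grid <- tidyr::expand_grid(
      rater_id = unique(as.character(records$rater_id)),
      key_dv = unique(paste(records$doc_id, records$version, sep = "\r")),
      indicator_id = as.integer(indicators)
    )
    grid <- tidyr::separate(grid, "key_dv", c("doc_id", "version"), sep = "\r")
    have <- paste(records$rater_id, records$doc_id, records$version,
                  records$indicator_id, sep = "\r")
    want <- paste(grid$rater_id, grid$doc_id, grid$version, grid$indicator_id,
                  sep = "\r")
    gap <- which(!want %in% have)
    if (length(gap) > 0) {
      v[[length(v) + 1L]] <- tibble::tibble(
        type = "incomplete",
        rater_id = grid$rater_id[gap],
        doc_id = grid$doc_id[gap],
        version = grid$version[gap],
        indicator_id = grid$indicator_id[gap],
        message = "missing rubric cell"
      )
    }
  }
  if (length(v) == 0) empty_violations() else dplyr::bind_rows(v)
}

#' Validate reader comprehension records
#'
#' Checks the six Likert columns are integers in 1–5, keys are unique, and —
#' when `check_complete` — every rater scored every observed document version.
#'
#' @inheritParams validate_expert_scores
#' @return A violations tibble as in [validate_expert_scores()]
#'   (`indicator_id` is `NA` for this schema).
#' @export
validate_reader_scores <- function(records, check_complete = TRUE) {
  assert_columns(records, reader_cols, "reader scale table")
  v <- list()
  for (dim in reader_dims) {
    x <- records[[dim]]
    bad <- which(is.na(x) | x != floor(x) | x < 1 | x > 5)
    if (length(bad) > 0) {
      v[[length(v) + 1L]] <- violation_rows(
        "range", records, bad, sprintf("%s=%s outside {1..5}", dim, x[bad])
      )
    }
  }
  key <- paste(records$rater_id, records$doc_id, records$version, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    v[[length(v) + 1L]] <- violation_rows("duplicate", records, dup,
                                          "duplicate (rater, doc, version) row")
  }
  if (check_complete) {
    grid <- tidyr::expand_grid(
      rater_id = unique(as.character(records$rater_id)),
      key_dv = unique(paste(records$doc_id, records$version, sep = "\r"))
    )
    grid <- tidyr::separate(grid, "key_dv", c("doc_id", "version"), sep = "\r")
    want <- paste(grid$rater_id, grid$doc_id, grid$version, sep = "\r")
    gap <- which(!want %in% key)
    if (length(gap) > 0) {
      v[[length(v) + 1L]] <- tibble::tibble(
        type = "incomplete", rater_id = grid$rater_id[gap],
        doc_id = grid$doc_id[gap], version = grid$version[gap],
        indicator_id = NA_integer_, message = "missing reader rating"
      )
    }
  }
  if (length(v) == 0) empty_violations() else dplyr::bind_rows(v)
}

violation_rows <- function(type, records, idx, message) {
  tibble::tibble(
    type = type,
    rater_id = as.character(records$rater_id[idx]),
    doc_id = as.character(records$doc_id[idx]),
    version = as.character(records$version[idx]),
    indicator_id = if ("indicator_id" %in% names(records)) {
      as.integer(records$indicator_id[idx])
    } else {
      NA_integer_
    },
    message = message
  )
}

empty_violations <- function() {
  tibble::tibble(
    type = character(), rater_id = character(), doc_id = character(),
    version = character(), indicator_id = integer(), message = character()
  )
}

stop_on_violations <- function(report) {
  if (nrow(report) > 0) {
    head_msgs <- utils::head(sprintf(
      "[%s] rater=%s doc=%s version=%s: %s",
      report$type, report$rater_id, report$doc_id, report$version, report$message
    ), 5)
    abort_validation(paste(
      c(sprintf("score table has %d violation(s):", nrow(report)), head_msgs),
      collapse = "\n"
    ))
  }
  invisible(report)
}

#' Write a score table to CSV
#'
#' @param records A score tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
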