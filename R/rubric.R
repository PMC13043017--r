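# The 20-indicator content-quality framework and its aggregation rules.

indicator_names <- c(
  "confidentiality",
  "exceptions to confidentiality",
  "client rights",
  "guardian consent",
  "goals and scope",
  "format and frequency",
  "fees and cancelation policy",
  "recording methods",
  "authorization and revocation",
  "crisis procedures",
  "complaints and appeals",
  "data protection",
  "disclaimer of boundaries",
  "language clarity",
  "voluntariness",
  "client obligations",
  "counseling limitations",
  "counselor qualifications",
  "counseling modalities",
  "target population"
)

#' The content-quality indicator codebook
#'
#' The rubric covers 20 core elements an informed consent form for counseling
#' is expected to contain. Each indicator is scored on three dimensions:
#' existence (0–1, is the element presented as an independent item),
#' specificity (0–2, are concrete details given) and operability (0–2, are
#' actionable procedures specified) — at most 5 points per indicator, 100 in
#' total, with dimension subscores of 20/40/40. Scoring is human work; the
#' package validates and aggregates.
#'
#' @param codebook_path Optional path to a codebook CSV with columns
#'   `indicator_id`, `name` and anchor descriptions; defaults to the copy
#'   shipped in `inst/extdata/codebook.csv`.
#' @return A tibble with one row per indicator.
#' @export
icf_indicators <- function(codebook_path = NULL) {
  path <- codebook_path %||%
    system.file("extdata", "codebook.csv", package = "icfeval")
  if (nzchar(path) && file.exists(path)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    df$indicator_id <- as.integer(df$indicator_id)
    return(tibble::as_tibble(df))
  }
  tibble::tibble(indicator_id = 1:20, name = indicator_names)
}

#' Aggregate expert rubric scores per document version
#'
#' Per rater and document version the three dimensions are summed over the 20
#' indicators (existence subtotal of at most 20, specificity and operability
#' of at most 40 each, total of at most 100); rater totals are then averaged
#' per document version. Averaging across raters happens after the
#' within-rater sums, and nothing is ever rounded.
#'
#' @param records Expert rubric records (long format, see
#'   [read_score_table()]).
#' @param by_rater Keep per-rater aggregates (one row per rater x document x
#'   version) instead of averaging across raters — the shape consumed by
#'   [fit_lmm()] and [icc2k()].
#' @param allow_partial If `FALSE` (default) any missing rubric cell is an
#'   error. If `TRUE`, a rater missing any indicator for a document is dropped
#'   for that document (never rescaled or imputed).
#' @param indicators Expected indicator ids.
#' @return A tibble with `doc_id`, `version` (plus `rater_id` when
#'   `by_rater`), `existence`, `specificity`, `operability`, `total`.
#' @export
aggregate_expert <- function(records, by_rater = FALSE, allow_partial = FALSE,
                             indicators = 1:20) {
  if (is.null(records) || nrow(records) == 0) {
    abort_degenerate("no expert records to aggregate")
  }
  report <- validate_expert_scores(records, check_complete = TRUE,
                                   indicators = indicators)
  gaps <- report[report$type == "incomplete", ]
  hard <- report[report$type != "incomplete", ]
  if (nrow(hard) > 0) stop_on_violations(hard)
  if (nrow(gaps) > 0 && !allow_partial) stop_on_violations(gaps)

  per_rater <- records |>
    dplyr::group_by(.data$rater_id, .data$doc_id, .data$version) |>
    dplyr::summarise(
      existence = sum(.data$existence),
      specificity = sum(.data$specificity),
      operability = sum(.data$operability),
      n_ind = dplyr::n(),
      .groups = "drop"
    )
  if (nrow(gaps) > 0) {
    # drop incomplete rater-document pairs rather than rescale
    per_rater <- per_rater[per_rater$n_ind == length(indicators), ]
    if (nrow(per_rater) == 0) abort_degenerate("no complete rater-document aggregates remain")
  }
  per_rater$n_ind <- NULL
  per_rater$total <- per_rater$existence + per_rater$specificity + per_rater$operability
  if (by_rater) {
    return(per_rater)
  }
  per_rater |>
    dplyr::group_by(.data$doc_id, .data$version) |>
    dplyr::summarise(
      existence = mean(.data$existence),
      specificity = mean(.data$specificity),
      operability = mean(.data$operability),
      total = mean(.data$total),
      .groups = "drop"
    )
}

#' Aggregate reading-comprehension scores per document version
#'
#' Each of the six Likert dimensions is averaged across raters per document
#' version; the total is the sum of the six dimension means (range 6–30) and
#' `dimension_means` is `total / 6` (range 1–5).
#'
#' @param records Reader scale records (see [read_score_table()]).
#' @param by_rater Keep per-rater rows (total per rater = sum of the six raw
#'   ratings) instead of averaging — the shape for [fit_lmm()] / [icc2k()].
#' @return A tibble with `doc_id`, `version` (plus `rater_id` when
#'   `by_rater`), the six dimensions, `total` and `dimension_means`.
#' @export
aggregate_comprehension <- function(records, by_rater = FALSE) {
  if (is.null(records) || nrow(records) == 0) {
    abort_degenerate("no reader records to aggregate")
  }
  stop_on_violations(validate_reader_scores(records, check_complete = FALSE))
  if (by_rater) {
    out <- dplyr::select(records, dplyr::all_of(reader_cols))
    out$total <- rowSums(out[reader_dims])
    out$dimension_means <- out$total / 6
    return(tibble::as_tibble(out))
  }
  records |>
    dplyr::group_by(.data$doc_id, .data$version) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(reader_dims), mean),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      total = rowSums(dplyr::pick(dplyr::all_of(reader_dims))),
      dimension_means = .data$total / 6
    )
}

#' Per-indicator score profile
#'
#' Mean of each rubric dimension (and their sum) per indicator and version,
#' averaged over raters and documents — the data behind indicator-level
#' heatmaps. Summing the profile over indicators reproduces the version means
#' of the [aggregate_expert()] subtotals exactly.
#'
#' @param records Expert rubric records.
#' @return A tibble with one row per (indicator, version): `indicator_id`,
#'   `name`, `version`, `existence`, `specificity`, `operability`, `total`.
#' @export
indicator_profile <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    abort_degenerate("no expert records to profile")
  }
  report <- validate_expert_scores(records, check_complete = FALSE)
  stop_on_violations(report[report$type != "incomplete", ])
  defs <- icf_indicators()[, c("indicator_id", "name")]
  records |>
    dplyr::group_by(.data$indicator_id, .data$version) |>
    dplyr::summarise(
      existence = mean(.data$existence),
      specificity = mean(.data$specificity),
      operability = mean(.data$operability),
      .groups = "drop"
    ) |>
    dplyr::mutate(total = .data$existence + .data$specificity + .data$operability) |>
    dplyr::left_join(defs, by = "indicator_id") |>
    dplyr::relocate("indicator_id", "name", "version")
}
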