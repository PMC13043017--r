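#' Intraclass correlation ICC(2,k)
#'
#' Inter-rater reliability of a rater panel's mean score: the Shrout-Fleiss
#' form 2, average-measures, absolute-agreement intraclass correlation for a
#' two-way random-effects design (every rater rates every target). Computed
#' from the two-way ANOVA mean squares
#' \deqn{ICC(2,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)}
#' with \eqn{MS_R} the between-target, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square over `n` targets. The confidence
#' interval is the standard F-based interval for the single-measure form,
#' Spearman-Brown-stepped up to `k` raters.
#'
#' @param ratings Numeric matrix with targets (documents) in rows and raters
#'   in columns; complete (no `NA`, no imputation).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A one-row tibble: `form` (`"ICC(2,k)"`), `value`, `ci_low`,
#'   `ci_high`, `k`, `n_targets`, and the three mean squares `ms_rows`,
#'   `ms_cols`, `ms_error`.
#' @export
#' @examples
#' m <- cbind(r1 = c(1, 2, 3, 4), r2 = c(1.5, 2.5, 2.8, 4.1), r3 = c(1, 2, 3.5, 4))
#' icc2k(m)
icc2k <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) abort_validation("ratings matrix contains missing cells; no imputation is performed")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (k < 2) abort_validation("need at least 2 raters")
  if (n < 2) abort_validation("need at least 2 targets")

  gm <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - gm)^2)
  ss_cols <- n * sum((col_m - gm)^2)
  ss_total <- sum((ratings - gm)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- max(0, ss_err) / ((n - 1) * (k - 1))

  if (ms_rows <= 0) {
    abort_degenerate("zero between-target variance; ICC undefined for a constant panel")
  }

  value <- (ms_rows - ms_err) / (ms_rows + (ms_cols - ms_err) / n)
  icc1 <- (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err + k * (ms_cols - ms_err) / n)

  alpha <- 1 - conf_level
  if (1 - icc1 < .Machine$double.eps^0.5) {
    # perfect agreement: interval collapses to the point value
    ci <- c(value, value)
  } else {
    a <- k * icc1 / (n * (1 - icc1))
    b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
    v <- (a * ms_cols + b * ms_err)^2 /
      ((a * ms_cols)^2 / (k - 1) + (b * ms_err)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    low1 <- n * (ms_rows - f_l * ms_err) /
      (f_l * (k * ms_cols + (k * n - k - n) * ms_err) + n * ms_rows)
    up1 <- n * (f_u * ms_rows - ms_err) /
      (k * ms_cols + (k * n - k - n) * ms_err + n * f_u * ms_rows)
    sb <- function(r1) k * r1 / (1 + (k - 1) * r1)
    ci <- c(sb(low1), sb(up1))
  }

  tibble::tibble(
    form = "ICC(2,k)", value = value, ci_low = ci[1], ci_high = ci[2],
    k = as.integer(k), n_targets = as.integer(n),
    ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_err
  )
}

#' Panel reliability of per-rater totals
#'
#' Convenience wrapper: pivots a long per-rater aggregate table (one row per
#' rater x document x version, as produced by `aggregate_expert(by_rater =
#' TRUE)` or `aggregate_comprehension(by_rater = TRUE)`) into the
#' document-version x rater matrix over all evaluation units and applies
#' [icc2k()] to the chosen outcome.
#'
#' @param records Long tibble with `rater_id`, `doc_id`, `version` and the
#'   outcome column.
#' @param outcome Name of the outcome column (default `"total"`).
#' @param conf_level Confidence level.
#' @return See [icc2k()].
#' @export
icc_panel <- function(records, outcome = "total", conf_level = 0.95) {
  assert_columns(records, c("rater_id", "doc_id", "version", outcome),
                 "per-rater aggregate table")
  wide <- tidyr::pivot_wider(
    records[, c("rater_id", "doc_id", "version", outcome)],
    names_from = "rater_id", values_from = dplyr::all_of(outcome)
  )
  mat <- as.matrix(wide[, setdiff(names(wide), c("doc_id", "version"))])
  icc2k(mat, conf_level = conf_level)
}
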