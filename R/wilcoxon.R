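#' Paired Wilcoxon signed-rank test with effect size
#'
#' Two-sided paired signed-rank test. Zero differences are discarded by
#' default (Wilcoxon's rule, `zero_method = "wilcox"`; the Pratt variant keeps
#' them in the ranking). With at most 25 usable pairs and no tied absolute
#' differences the exact null distribution of the positive-rank sum is used
#' (via [stats::psignrank()]); otherwise the normal approximation with
#' continuity and tie correction. The effect size is `r = |z| / sqrt(n)` with
#' `n` the number of non-zero differences; on the exact branch `z` is
#' back-computed from the exact p-value so `r` stays defined.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @param zero_method `"wilcox"` (discard zero differences) or `"pratt"`.
#' @param exact_max Largest `n` for which the exact branch is used (default
#'   25; the `"pratt"` method always uses the approximation).
#' @return A one-row tibble: `n` (non-zero pairs), `statistic` (positive-rank
#'   sum V), `z`, `p_raw`, `effect_r`, `method`, `zero_method`.
#' @export
#' @examples
#' wilcoxon_paired(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
wilcoxon_paired <- function(x, y, zero_method = c("wilcox", "pratt"),
                            exact_max = 25L) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y)) {
    abort_validation(sprintf("x (%d) and y (%d) differ in length", length(x), length(y)))
  }
  if (anyNA(x) || anyNA(y)) abort_validation("paired values must not contain NA")
  d <- as.numeric(x) - as.numeric(y)
  nonzero <- d != 0
  n <- sum(nonzero)
  if (n == 0) abort_degenerate("all paired differences are zero")

  if (zero_method == "wilcox") {
    dd <- d[nonzero]
    r <- rank(abs(dd))
    v <- sum(r[dd > 0])
    ties <- any(duplicated(abs(dd)))
    if (!ties && n <= exact_max) {
      p_low <- stats::psignrank(v, n)
      p_high <- stats::psignrank(v - 1, n, lower.tail = FALSE)
      p <- min(1, 2 * min(p_low, p_high))
      mu <- n * (n + 1) / 4
      z_abs <- stats::qnorm(p / 2, lower.tail = FALSE)
      z <- sign(v - mu) * z_abs
      if (v == mu) z <- 0
      return(comparison_row(n, v, z, p, "exact", zero_method))
    }
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  } else {
    # Pratt: rank |d| including zeros, drop zero ranks from the statistic
    r_all <- rank(abs(d))
    v <- sum(r_all[d > 0])
    n0 <- sum(!nonzero)
    n_all <- length(d)
    mu <- (n_all * (n_all + 1) - n0 * (n0 + 1)) / 4
    tie_tab <- table(r_all[nonzero])
    sigma2 <- n_all * (n_all + 1) * (2 * n_all + 1) / 24 -
      n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
  }
  if (sigma2 <= 0) abort_degenerate("zero variance in signed-rank statistic")
  cc <- sign(v - mu) * 0.5 # continuity correction toward the mean
  z <- (v - mu - cc) / sqrt(sigma2)
  if (v == mu) z <- 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  comparison_row(n, v, z, p, "normal", zero_method)
}

comparison_row <- function(n, v, z, p, method, zero_method) {
  tibble::tibble(
    n = as.integer(n), statistic = v, z = z, p_raw = p,
    effect_r = abs(z) / sqrt(n), method = method, zero_method = zero_method
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, capped at 1. When
#' `family` is given, adjustment is applied independently within each family
#' (the grouping policy for which tests form one multiplicity family is a
#' configuration decision, not a property of the data).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param family Optional grouping vector (same length as `p`).
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
bh_fdr <- function(p, family = NULL) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort_validation("p-values must lie in [0, 1] and contain no NA")
  }
  if (is.null(family)) {
    return(stats::p.adjust(p, method = "BH"))
  }
  if (length(family) != length(p)) {
    abort_validation("family grouping must match p-values in length")
  }
  out <- numeric(length(p))
  for (g in unique(family)) {
    idx <- which(family == g)
    out[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  out
}

#' Pairwise version comparisons for a table of outcomes
#'
#' For every outcome column and every (ordered) pair of document versions,
#' runs the paired Wilcoxon signed-rank test on documents present in both
#' versions and adjusts p-values by Benjamini-Hochberg under the configured
#' family policy. Pairs whose differences are all zero are flagged degenerate
#' (with `NA` p-values) rather than failing the whole table. Also returns the
#' per-version mean/SD summary that conventionally accompanies such
#' comparison tables.
#'
#' @param values A tibble with `doc_id`, `version` and one numeric column per
#'   outcome (e.g. the output of [compute_text_metrics()] or
#'   [aggregate_expert()]).
#' @param outcomes Character vector of outcome columns; defaults to all
#'   numeric columns other than the keys.
#' @param versions Version ordering; defaults to order of appearance.
#' @param fdr_family Multiplicity family policy: `"block"` (all tests in this
#'   call adjusted together, the default), `"outcome"` (the three version
#'   pairs of each outcome form a family), `"pair"`, or `"none"`.
#' @param zero_method Passed to [wilcoxon_paired()].
#' @return A list of class `icf_comparison`: `summary` (mean/SD per outcome
#'   and version) and `comparisons` (one row per outcome and version pair
#'   with `n`, `statistic`, `z`, `p_raw`, `p_fdr`, `effect_r`, `degenerate`).
#' @export
compare_versions <- function(values, outcomes = NULL, versions = NULL,
                             fdr_family = c("block", "outcome", "pair", "none"),
                             zero_method = "wilcox") {
  fdr_family <- match.arg(fdr_family)
  assert_columns(values, c("doc_id", "version"), "outcome table")
  if (is.null(outcomes)) {
    outcomes <- names(values)[vapply(values, is.numeric, logical(1))]
    outcomes <- setdiff(outcomes, c("doc_id", "version", "rater_id", "indicator_id"))
  }
  if (length(outcomes) == 0) abort_validation("no outcome columns to compare")
  versions <- versions %||% unique(values$version)
  if (length(versions) < 2) abort_validation("need at least two versions to compare")
  pairs <- utils::combn(versions, 2, simplify = FALSE)

  summary <- values |>
    dplyr::group_by(.data$version) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(outcomes), list(mean = mean, sd = stats::sd)),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"version",
      names_to = c("outcome", "stat"), names_pattern = "(.*)_(mean|sd)"
    ) |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")

  rows <- list()
  for (outcome in outcomes) {
    for (pair in pairs) {
      a <- values[values$version == pair[2], c("doc_id", outcome)]
      b <- values[values$version == pair[1], c("doc_id", outcome)]
      m <- merge(a, b, by = "doc_id", suffixes = c(".a", ".b"))
      base <- tibble::tibble(
        outcome = outcome,
        pair = sprintf("%s vs %s", pair[2], pair[1]),
        version_a = pair[2], version_b = pair[1]
      )
      res <- tryCatch(
        cbind(base,
              wilcoxon_paired(m[[paste0(outcome, ".a")]], m[[paste0(outcome, ".b")]],
                              zero_method = zero_method),
              degenerate = FALSE),
        icfeval_degenerate_error = function(e) {
          cbind(base,
                tibble::tibble(n = 0L, statistic = NA_real_, z = NA_real_,
                               p_raw = NA_real_, effect_r = NA_real_,
                               method = NA_character_, zero_method = zero_method),
                degenerate = TRUE)
        }
      )
      rows[[length(rows) + 1L]] <- res
    }
  }
  comparisons <- tibble::as_tibble(dplyr::bind_rows(rows))
  ok <- !is.na(comparisons$p_raw)
  comparisons$p_fdr <- NA_real_
  if (any(ok)) {
    fam <- switch(fdr_family,
      block = rep("all", sum(ok)),
      outcome = comparisons$outcome[ok],
      pair = comparisons$pair[ok],
      none = NULL
    )
    comparisons$p_fdr[ok] <- if (fdr_family == "none") {
      comparisons$p_raw[ok]
    } else {
      bh_fdr(comparisons$p_raw[ok], fam)
    }
  }
  structure(
    list(summary = summary, comparisons = comparisons, fdr_family = fdr_family),
    class = "icf_comparison"
  )
}

#' @export
print.icf_comparison <- function(x, ...) {
  cat(sprintf("<icf_comparison> %d comparison(s), FDR family: %s\n",
              nrow(x$comparisons), x$fdr_family))
  print(x$comparisons, ...)
  invisible(x)
}
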