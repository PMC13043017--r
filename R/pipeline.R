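# End-to-end orchestration and report serialisation.

default_stages <- list(metrics = TRUE, rubric = TRUE, comprehension = TRUE,
                       wilcoxon = TRUE, icc = TRUE, lmm = TRUE)
default_stats <- list(fdr_family = "block", wilcoxon_zero_method = "wilcox",
                      lmm_reference = "original")

#' Run the full evaluation pipeline
#'
#' Orchestrates the three evaluation dimensions over one corpus: text metrics
#' with pairwise version comparisons, expert content-quality aggregation with
#' comparisons, panel reliability and mixed-model contrasts (existence,
#' specificity, operability, total), and reading-comprehension aggregation
#' with the same statistical layer (six dimensions, total, dimension means).
#' Every under-specified analysis knob in effect (segmenter, Lee-Yang
#' weights, FDR family, zero-difference handling, LMM reference) is echoed in
#' the report header so results are auditable from the report alone.
#'
#' @param config A configuration list (or path to a YAML file, see
#'   [read_pipeline_config()]). Keys: `versions`; `stages` (logical toggles
#'   `metrics`, `rubric`, `comprehension`, `wilcoxon`, `icc`, `lmm`); `stats`
#'   (`fdr_family`, `wilcoxon_zero_method`, `lmm_reference`); `text`
#'   ([text_config()] overrides); either `synthetic` (a list of
#'   [synth_config()] arguments, or `TRUE` for its defaults) or `paths`
#'   (`manifest`, `polite_lexicon`, `harsh_lexicon`, `expert_scores`,
#'   `reader_scores`); and `seed` (used only by the synthetic stage).
#' @return A list of class `icf_report` with sections `config`, `metrics`,
#'   `quality` and `comprehension`; disabled stages yield `NULL` sections.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stages <- utils::modifyList(default_stages, config$stages %||% list())
  stats_opts <- utils::modifyList(default_stats, config$stats %||% list())
  versions <- config$versions %||% c("original", "chatgpt5", "grok4")
  seed <- config$seed

  corpus <- NULL; lex <- NULL; tcfg <- NULL
  expert_records <- NULL; reader_records <- NULL

  if (!is.null(config$synthetic)) {
    synth_args <- if (isTRUE(config$synthetic)) list() else config$synthetic
    synth_args$versions <- synth_args$versions %||% versions
    scfg <- do.call(synth_config, synth_args)
    seed <- seed %||% 1L
    gen <- generate_corpus(scfg, seed = seed)
    corpus <- gen$corpus
    lex <- gen$lexicon
    tcfg <- gen$text_config
    expert_records <- generate_expert_scores(scfg, seed = seed + 1L)$records
    reader_records <- generate_reader_scores(scfg, seed = seed + 2L)$records
  } else if (!is.null(config$paths)) {
    paths <- config$paths
    if (stages$metrics) {
      corpus <- read_corpus(paths$manifest, versions = versions)
      lex <- read_lexicon(paths$polite_lexicon, paths$harsh_lexicon)
      text_over <- config$text %||% list()
      if (!is.null(paths$dictionary)) {
        text_over$segmenter <- list(name = "greedy",
                                    dictionary = read_term_list(paths$dictionary))
      }
      tcfg <- do.call(text_config, text_over)
    }
    if (stages$rubric && !is.null(paths$expert_scores)) {
      expert_records <- read_score_table(paths$expert_scores, "expert_rubric")
    }
    if (stages$comprehension && !is.null(paths$reader_scores)) {
      reader_records <- read_score_table(paths$reader_scores, "reader_scale")
    }
  }

  report <- list(
    config = list(
      versions = versions,
      stages = stages,
      stats = stats_opts,
      seed = seed,
      text = if (!is.null(tcfg)) {
        list(
          sentence_delimiters = tcfg$sentence_delimiters,
          nesting = tcfg$nesting,
          leeyang_weights = as.list(tcfg$leeyang$weights),
          segmenter = tcfg$segmenter$name %||% "custom"
        )
      },
      synthetic = !is.null(config$synthetic)
    ),
    metrics = NULL, quality = NULL, comprehension = NULL
  )

  if (stages$metrics && !is.null(corpus)) {
    tab <- compute_text_metrics(corpus, lex, tcfg)
    section <- list(table = tab)
    if (stages$wilcoxon) {
      cmp <- compare_versions(tab, versions = versions,
                              fdr_family = stats_opts$fdr_family,
                              zero_method = stats_opts$wilcoxon_zero_method)
      section$summary <- cmp$summary
      section$comparisons <- cmp$comparisons
    }
    report$metrics <- section
  }

  if (stages$rubric && !is.null(expert_records)) {
    report$quality <- score_section(
      per_rater = aggregate_expert(expert_records, by_rater = TRUE),
      per_doc = aggregate_expert(expert_records),
      outcomes = c("existence", "specificity", "operability", "total"),
      versions = versions, stages = stages, stats_opts = stats_opts
    )
    report$quality$indicator_profile <- indicator_profile(expert_records)
  }

  if (stages$comprehension && !is.null(reader_records)) {
    report$comprehension <- score_section(
      per_rater = aggregate_comprehension(reader_records, by_rater = TRUE),
      per_doc = aggregate_comprehension(reader_records),
      outcomes = c(reader_dims, "total", "dimension_means"),
      versions = versions, stages = stages, stats_opts = stats_opts
    )
  }

  structure(report, class = "icf_report")
}

score_section <- function(per_rater, per_doc, outcomes, versions, stages,
                          stats_opts) {
  section <- list(aggregates = per_doc)
  if (stages$wilcoxon) {
    cmp <- compare_versions(per_doc, outcomes = outcomes, versions = versions,
                            fdr_family = stats_opts$fdr_family,
                            zero_method = stats_opts$wilcoxon_zero_method)
    section$summary <- cmp$summary
    section$comparisons <- cmp$comparisons
  }
  if (stages$icc) {
    section$icc <- icc_panel(per_rater, outcome = "total")
  }
  if (stages$lmm) {
    fits <- lapply(outcomes, function(o) {
      fit_lmm(per_rater, outcome = o, reference = stats_opts$lmm_reference)
    })
    section$lmm_contrasts <- dplyr::bind_rows(lapply(fits, `[[`, "contrasts"))
    section$lmm_varcomp <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
      tibble::tibble(
        outcome = outcomes[i],
        var_doc = fits[[i]]$varcomp[["doc"]],
        var_rater = fits[[i]]$varcomp[["rater"]],
        var_residual = fits[[i]]$varcomp[["residual"]],
        singular = fits[[i]]$singular,
        logLik = fits[[i]]$logLik
      )
    }))
  }
  section
}

#' @export
print.icf_report <- function(x, ...) {
  on_off <- vapply(x$config$stages, isTRUE, logical(1))
  cat("<icf_report>\n")
  cat("  stages:", paste(names(on_off)[on_off], collapse = ", "), "\n")
  for (s in c("metrics", "quality", "comprehension")) {
    if (!is.null(x[[s]])) {
      cat(sprintf("  %s: %s\n", s, paste(names(x[[s]]), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Write an analysis report
#'
#' Serialises a result bundle to machine-readable form. `format = "json"`
#' writes one JSON file with full numeric precision, so that reading it back
#' reproduces every number exactly. `format = "csv"` writes each tabular
#' section as a CSV file under `path` (treated as a directory) plus a
#' `config.json` header.
#'
#' @param report An `icf_report` from [run_pipeline()], or any list of
#'   tibbles/values with a comparable shape.
#' @param path Output file (json) or directory (csv).
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  report <- unclass(report)
  if (format == "json") {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    ok <- tryCatch({
      jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                           na = "null", null = "null", pretty = TRUE)
      TRUE
    }, error = function(e) abort_io(sprintf("cannot write report: %s", conditionMessage(e))))
    return(invisible(path))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort_io(sprintf("cannot create report directory: %s", path))
  jsonlite::write_json(report$config, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", null = "null",
                       pretty = TRUE)
  for (section in setdiff(names(report), "config")) {
    for (tab in names(report[[section]])) {
      obj <- report[[section]][[tab]]
      if (is.data.frame(obj)) {
        utils::write.csv(obj, file.path(path, sprintf("%s_%s.csv", section, tab)),
                         row.names = FALSE, fileEncoding = "UTF-8")
      }
    }
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' Inverse of [write_report()] for the JSON format; tabular sections are
#' restored as tibbles.
#'
#' @param path Path to a report JSON file.
#' @return A list of class `icf_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("report not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  restore <- function(x) {
    if (is.data.frame(x)) return(tibble::as_tibble(x))
    if (is.list(x)) return(lapply(x, restore))
    x
  }
  structure(restore(raw), class = "icf_report")
}
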