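#' Default text-analysis configuration
#'
#' Bundles every tunable knob of the text pipeline in one list so that an
#' analysis is reproducible from its configuration alone: sentence delimiters,
#' the nested-sentence classifier, Lee-Yang composite weights, and the word
#' segmenter. Values can be overridden piecemeal via `...`.
#'
#' @details
#' * `sentence_delimiters`: characters that terminate a sentence. Defaults to
#'   the CJK terminal punctuation marks (ideographic full stop, exclamation,
#'   question mark, ellipsis, semicolon) and their ASCII equivalents
#'   `. ! ? ;`; hard newlines always split.
#' * `nesting`: `markers` is a character vector of two-character open/close
#'   pairs (brackets and quotation marks) whose paired presence marks an
#'   embedded clause; `separator_threshold` (default 3) is the minimum number
#'   of internal clause separators (ideographic comma, enumeration comma,
#'   colon, ASCII comma) that alone classifies a sentence as nested.
#' * `leeyang`: weights of the readability composite, see [lee_yang_index()].
#' * `segmenter`: `name` is `"greedy"` (dictionary longest-match, requires
#'   `dictionary`, a character vector of words) or `"whitespace"` for
#'   pre-segmented text.
#'
#' @param ... named overrides merged over the defaults (one level deep for
#'   the `nesting`, `leeyang` and `segmenter` sublists).
#' @return A named list of class `icf_config`.
#' @export
#' @examples
#' cfg <- text_config(leeyang = list(weights = c(sentence = 1, word = 1, lex = 1)))
#' cfg$leeyang$weights
text_config <- function(...) {
  cfg <- list(
    # CJK: 。 full stop, ！ !, ？ ?, … ellipsis, ； ;
    sentence_delimiters = c(
      "。", "！", "？", "…", "；",
      ".", "!", "?", ";"
    ),
    nesting = list(
      # open/close pairs: fullwidth parens, ASCII parens, angle/corner/lenticular
      # brackets, curly and single quotation marks, square brackets
      markers = c(
        "（）", "()", "《》", "「」",
        "『』", "【】", "“”", "‘’", "[]"
      ),
      # ideographic comma, enumeration comma, fullwidth colon, ASCII comma
      separators = c("，", "、", "：", ","),
      separator_threshold = 3L
    ),
    leeyang = list(
      weights = c(sentence = 1, word = 10, lex = 0.1)
    ),
    segmenter = list(
      name = "greedy",
      dictionary = NULL
    )
  )
  overrides <- list(...)
  for (key in names(overrides)) {
    if (is.list(cfg[[key]]) && is.list(overrides[[key]])) {
      for (sub in names(overrides[[key]])) cfg[[key]][[sub]] <- overrides[[key]][[sub]]
    } else {
      cfg[[key]] <- overrides[[key]]
    }
  }
  structure(cfg, class = "icf_config")
}

#' Read a pipeline configuration file
#'
#' Reads a YAML configuration for [run_pipeline()] / the command-line
#' interface. Recognised top-level keys: `paths` (manifest, lexicon files,
#' score tables, output directory), `versions`, `stages`, `stats`
#' (`fdr_family`, `wilcoxon_zero_method`, `lmm_reference`), `text`
#' (overrides for [text_config()]) and `synthetic` (see [synth_config()]).
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}
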