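#' Split text into sentences
#'
#' Sentences are delimited by terminal punctuation (configurable; defaults to
#' the CJK full stop, exclamation and question marks, ellipsis and semicolon
#' plus their ASCII equivalents) and by hard newlines. Runs of consecutive
#' delimiters stay attached to the preceding sentence; empty fragments are
#' dropped. Text containing no delimiter at all is one sentence.
#'
#' @param text A length-1 character string.
#' @param config A [text_config()] list (uses `$sentence_delimiters`).
#' @return Character vector of sentences, each retaining its trailing
#'   delimiter(s).
#' @export
#' @examples
#' split_sentences("First point. Second one! Third")
split_sentences <- function(text, config = text_config()) {
  if (length(text) != 1 || is.na(text)) {
    abort_validation("`text` must be a single non-NA string")
  }
  if (!nzchar(trimws(text))) {
    abort_degenerate("text contains no retained characters")
  }
  delims <- paste(vapply(config$sentence_delimiters, esc_regex, character(1)),
                  collapse = "")
  cls <- paste0("[", delims, "]")
  # split after a run of delimiters (run stays with the preceding sentence)
  pattern <- paste0("(?<=", cls, ")(?!", cls, ")")
  pieces <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  pieces <- unlist(strsplit(pieces, pattern, perl = TRUE), use.names = FALSE)
  pieces <- trimws(pieces)
  pieces[nzchar(pieces)]
}

esc_regex <- function(ch) {
  if (grepl("[][\\^$.|?*+(){}-]", ch)) paste0("\\", ch) else ch
}

# Characters never part of a word: Unicode punctuation, symbols, whitespace.
PUNCT_REGEX <- "[\\p{P}\\p{S}\\s]+"

#' Word segmenters
#'
#' Word segmentation is a pluggable contract: a segmenter is any function
#' taking one punctuation-free character run and returning its ordered word
#' vector. Two implementations ship with the package:
#'
#' * `segmenter_whitespace()` treats whitespace-separated tokens as words —
#'   for pre-segmented or alphabetic text (punctuation is already stripped
#'   upstream, so a run is a single token by the time it reaches the
#'   segmenter).
#' * `segmenter_greedy(dictionary)` performs greedy (maximum-munch)
#'   longest-match against a word dictionary, the classic baseline for
#'   unspaced Chinese text; characters matching no dictionary entry become
#'   single-character words.
#'
#' @param dictionary Character vector of dictionary words (non-empty).
#' @return A function `character(1) -> character()`.
#' @export
#' @examples
#' seg <- segmenter_greedy(c("aa", "bb"))
#' seg("aabbc")
segmenter_greedy <- function(dictionary) {
  dictionary <- unique(dictionary[nzchar(dictionary)])
  if (length(dictionary) == 0) abort_config("greedy segmenter needs a non-empty dictionary")
  lens <- nchar(dictionary)
  max_len <- max(lens)
  dict_env <- new.env(parent = emptyenv(), size = length(dictionary) * 2L)
  for (w in dictionary) assign(w, TRUE, envir = dict_env)
  function(run) {
    chars <- strsplit(run, "", fixed = TRUE)[[1]]
    n <- length(chars)
    out <- character(0)
    i <- 1L
    while (i <= n) {
      matched <- 1L
      for (l in seq(min(max_len, n - i + 1L), 1L)) {
        cand <- paste(chars[i:(i + l - 1L)], collapse = "")
        if (exists(cand, envir = dict_env, inherits = FALSE)) {
          matched <- l
          break
        }
      }
      out <- c(out, paste(chars[i:(i + matched - 1L)], collapse = ""))
      i <- i + matched
    }
    out
  }
}

#' @rdname segmenter_greedy
#' @export
segmenter_whitespace <- function() {
  function(run) {
    words <- strsplit(run, "\\s+")[[1]]
    words[nzchar(words)]
  }
}

resolve_segmenter <- function(config) {
  seg <- config$segmenter
  if (is.function(seg)) return(seg)
  switch(seg$name %||% "greedy",
    whitespace = segmenter_whitespace(),
    greedy = {
      if (is.null(seg$dictionary)) {
        abort_config("segmenter 'greedy' requires segmenter$dictionary")
      }
      segmenter_greedy(seg$dictionary)
    },
    abort_config(sprintf("unknown segmenter: %s", seg$name))
  )
}

#' Segment a sentence into words
#'
#' Strips punctuation, symbols and whitespace, then applies the segmenter to
#' each remaining character run. Returns `character(0)` for a sentence of
#' punctuation only.
#'
#' @param sentence A length-1 string.
#' @param segmenter A segmenter function, see [segmenter_greedy()].
#' @return Character vector of words (no empty strings).
#' @export
segment_words <- function(sentence, segmenter) {
  runs <- strsplit(gsub(PUNCT_REGEX, " ", sentence, perl = TRUE), " ", fixed = TRUE)[[1]]
  runs <- runs[nzchar(runs)]
  if (length(runs) == 0) return(character(0))
  words <- unlist(lapply(runs, segmenter), use.names = FALSE)
  words[nzchar(words)]
}

#' Tokenize one document
#'
#' Applies [split_sentences()] then [segment_words()] and returns the token
#' structure consumed by the metric functions.
#'
#' @param text Document text (length-1 string).
#' @param config A [text_config()]; its `segmenter` entry may also be a
#'   segmenter function directly.
#' @param doc_id,version Provenance labels carried along.
#' @return An object of class `icf_tokens`: list with `doc_id`, `version`,
#'   `sentences` (character vector) and `words` (list of character vectors,
#'   one per sentence; may be empty for punctuation-only sentences).
#' @export
tokenize_document <- function(text, config = text_config(), doc_id = NA_character_,
                              version = NA_character_) {
  segmenter <- resolve_segmenter(config)
  sentences <- split_sentences(text, config)
  words <- lapply(sentences, segment_words, segmenter = segmenter)
  structure(
    list(doc_id = doc_id, version = version, sentences = sentences, words = words),
    class = "icf_tokens"
  )
}

#' @export
print.icf_tokens <- function(x, ...) {
  cat(sprintf(
    "<icf_tokens> %s/%s: %d sentence(s), %d word(s)\n",
    x$doc_id, x$version, length(x$sentences), sum(lengths(x$words))
  ))
  invisible(x)
}
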