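#' Structural features of a tokenized document
#'
#' The five basic structural features: character count, word count, sentence
#' count, words per sentence and characters per word. Character count sums
#' the characters of the words themselves — punctuation and whitespace are
#' excluded, which keeps `characters_per_word = character_count / word_count`
#' self-consistent.
#'
#' @param tokens An `icf_tokens` object from [tokenize_document()].
#' @return A one-row tibble with columns `character_count`, `word_count`,
#'   `sentence_count`, `words_per_sentence`, `characters_per_word`.
#' @export
compute_structural <- function(tokens) {
  stopifnot(inherits(tokens, "icf_tokens"))
  n_sent <- length(tokens$sentences)
  if (n_sent == 0) abort_degenerate("document has no sentences")
  words <- unlist(tokens$words, use.names = FALSE)
  n_words <- length(words)
  if (n_words == 0) abort_degenerate("document has no words after segmentation")
  n_chars <- sum(nchar(words))
  tibble::tibble(
    character_count = n_chars,
    word_count = n_words,
    sentence_count = n_sent,
    words_per_sentence = n_words / n_sent,
    characters_per_word = n_chars / n_words
  )
}

#' Nested sentence ratio
#'
#' Fraction of sentences classified as syntactically nested — a proxy for
#' embedded-clause density. A sentence is nested when it contains at least one
#' paired embedding marker (an opening bracket/quote with its closing partner
#' after it), or when its internal clause-separator count reaches
#' `separator_threshold` (default 3). Both the marker pairs and the separator
#' set are configurable; the classifier is a declared operationalisation, not
#' a parse.
#'
#' @param tokens An `icf_tokens` object.
#' @param config A [text_config()] (uses the `nesting` sublist).
#' @return A fraction in `[0, 1]`.
#' @export
nested_sentence_ratio <- function(tokens, config = text_config()) {
  stopifnot(inherits(tokens, "icf_tokens"))
  n_sent <- length(tokens$sentences)
  if (n_sent == 0) abort_degenerate("document has no sentences")
  nested <- vapply(tokens$sentences, is_nested_sentence, logical(1),
                   nesting = config$nesting, USE.NAMES = FALSE)
  sum(nested) / n_sent
}

is_nested_sentence <- function(sentence, nesting) {
  for (pair in nesting$markers) {
    open <- substr(pair, 1, 1)
    close <- substr(pair, 2, 2)
    i <- regexpr(open, sentence, fixed = TRUE)
    if (i > 0) {
      rest <- substr(sentence, i + 1L, nchar(sentence))
      if (grepl(close, rest, fixed = TRUE)) return(TRUE)
    }
  }
  seps <- sum(vapply(
    nesting$separators,
    function(s) lengths(regmatches(sentence, gregexpr(s, sentence, fixed = TRUE))),
    numeric(1)
  ))
  seps >= nesting$separator_threshold
}

#' Lee-Yang readability index
#'
#' A weighted composite of three document-level readability components for
#' Chinese text — higher values mean harder text:
#' \deqn{LY = w_s \bar{S} + w_w \bar{W} + w_x X}
#' where \eqn{\bar{S}} is the mean number of words per sentence, \eqn{\bar{W}}
#' the mean number of characters per word, and \eqn{X} the lexical-complexity
#' proportion: the percentage (0–100) of words with at least two characters.
#' The published weight constants are not restated in most applied reports, so
#' they are configuration: the shipped default `(w_s, w_w, w_x) = (1, 10, 0.1)`
#' gives the three components comparable magnitude on typical consent-form
#' text; matching a specific published calibration requires supplying its
#' weights.
#'
#' @param tokens An `icf_tokens` object.
#' @param weights Named numeric vector `c(sentence=, word=, lex=)`; all
#'   non-negative, not all zero.
#' @return Non-negative scalar.
#' @export
lee_yang_index <- function(tokens, weights = text_config()$leeyang$weights) {
  stopifnot(inherits(tokens, "icf_tokens"))
  if (length(weights) != 3 || any(is.na(weights)) || any(weights < 0)) {
    abort_config("Lee-Yang weights must be three non-negative numbers")
  }
  if (all(weights == 0)) abort_config("at least one Lee-Yang weight must be positive")
  names(weights) <- names(weights) %||% c("sentence", "word", "lex")
  s <- compute_structural(tokens)
  words <- unlist(tokens$words, use.names = FALSE)
  lex_pct <- 100 * mean(nchar(words) >= 2)
  unname(
    weights[["sentence"]] * s$words_per_sentence +
      weights[["word"]] * s$characters_per_word +
      weights[["lex"]] * lex_pct
  )
}

#' Tone friendliness score
#'
#' A surface-level lexical tone proxy on a 0–5 scale. Occurrences of polite
#' (`n_p`) and harsh (`n_h`) lexicon terms are counted over the raw sentence
#' text; the normalised difference `(n_p - n_h) / sentence_count` is clamped
#' to `[-1, 1]` and mapped linearly onto `[0, 5]`:
#' `score = 2.5 * (clamp((n_p - n_h)/S, -1, 1) + 1)`.
#' Equal polite and harsh counts (including none of either) give the midpoint
#' 2.5. Matching is substring-based per sentence with longer terms tried
#' first and overlapping matches never double-counted, so the score does not
#' depend on the segmenter dialect.
#'
#' @param tokens An `icf_tokens` object.
#' @param lex An [lexicon()] object.
#' @return Scalar in `[0, 5]`.
#' @export
tone_friendliness <- function(tokens, lex) {
  stopifnot(inherits(tokens, "icf_tokens"), inherits(lex, "icf_lexicon"))
  n_sent <- length(tokens$sentences)
  if (n_sent == 0) abort_degenerate("document has no sentences")
  counts <- count_lexicon_terms(tokens$sentences, lex)
  raw <- (counts$polite - counts$harsh) / n_sent
  2.5 * (clamp(raw, -1, 1) + 1)
}

# Count polite/harsh term occurrences over raw sentence strings. Semantics
# are a left-to-right scan trying longer terms first: candidate matches of
# every term are located (vectorised over sentences), then swept per sentence
# in order of start position (ties broken by descending length), accepting
# only matches that do not overlap an already accepted one. Overlaps are
# never double-counted and one text position serves one category.
count_lexicon_terms <- function(sentences, lex) {
  terms <- c(lex$polite, lex$harsh)
  is_polite <- c(rep(TRUE, length(lex$polite)), rep(FALSE, length(lex$harsh)))
  lens <- nchar(terms)

  starts <- vector("list", length(sentences))
  t_len <- vector("list", length(sentences))
  t_pol <- vector("list", length(sentences))
  for (t in seq_along(terms)) {
    hits <- gregexpr(terms[t], sentences, fixed = TRUE)
    for (s in seq_along(sentences)) {
      pos <- hits[[s]]
      if (pos[1] != -1L) {
        starts[[s]] <- c(starts[[s]], as.integer(pos))
        t_len[[s]] <- c(t_len[[s]], rep(lens[t], length(pos)))
        t_pol[[s]] <- c(t_pol[[s]], rep(is_polite[t], length(pos)))
      }
    }
  }

  n_p <- 0L
  n_h <- 0L
  for (s in seq_along(sentences)) {
    st <- starts[[s]]
    if (is.null(st)) next
    ord <- order(st, -t_len[[s]])
    st <- st[ord]
    ln <- t_len[[s]][ord]
    pol <- t_pol[[s]][ord]
    last_end <- 0L
    for (i in seq_along(st)) {
      if (st[i] > last_end) {
        if (pol[i]) n_p <- n_p + 1L else n_h <- n_h + 1L
        last_end <- st[i] + ln[i] - 1L
      }
    }
  }
  list(polite = n_p, harsh = n_h)
}

#' Compute all eight text metrics for a corpus
#'
#' Runs the full standardized pipeline per document version: sentence split,
#' word segmentation, the five structural features, nested sentence ratio,
#' Lee-Yang index and tone friendliness. Deterministic given the
#' configuration; row order follows the input corpus.
#'
#' @param corpus A tibble with `doc_id`, `version`, `text` (see
#'   [read_corpus()]).
#' @param lex An [lexicon()] object.
#' @param config A [text_config()].
#' @return A tibble keyed by `(doc_id, version)` with the eight metric
#'   columns `character_count`, `word_count`, `sentence_count`,
#'   `words_per_sentence`, `characters_per_word`, `nested_sentence_ratio`,
#'   `lee_yang_index`, `tone_friendliness`.
#' @export
compute_text_metrics <- function(corpus, lex, config = text_config()) {
  assert_columns(corpus, c("doc_id", "version", "text"), "corpus")
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    tokens <- tokenize_document(corpus$text[i], config,
                                doc_id = corpus$doc_id[i],
                                version = corpus$version[i])
    dplyr::bind_cols(
      tibble::tibble(doc_id = corpus$doc_id[i], version = corpus$version[i]),
      compute_structural(tokens),
      tibble::tibble(
        nested_sentence_ratio = nested_sentence_ratio(tokens, config),
        lee_yang_index = lee_yang_index(tokens, config$leeyang$weights),
        tone_friendliness = tone_friendliness(tokens, lex)
      )
    )
  })
  dplyr::bind_rows(rows)
}
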