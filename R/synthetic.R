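# Synthetic corpus and rater-score generators.
#
# The generators emulate the study design the analysis layer assumes: a
# corpus of documents in several rewritten versions, a small expert panel
# scoring a 20-indicator rubric and a reader panel scoring six Likert
# dimensions, with version fixed effects and crossed document/rater random
# intercepts. Documents are assembled from a synthetic CJK-range vocabulary
# so every metric has an exactly known, constructively computed ground truth.

#' Synthetic study configuration
#'
#' Defaults encode the reference study conditions: 33 documents in 3 versions
#' (`original`, `chatgpt5`, `grok4`), 5 expert raters on the 20-indicator
#' rubric, 10 readers on the 6-dimension scale. Per-version text parameters
#' (mean sentence counts, words per sentence, single-character word share,
#' lexicon-term injection rates, nesting rates) and score-model means are set
#' to the magnitudes observed in real counseling consent-form corpora;
#' variance components give realistic — clearly imperfect — rater agreement.
#'
#' @param n_docs Number of documents (default 33).
#' @param versions Ordered version labels (default
#'   `c("original", "chatgpt5", "grok4")`).
#' @param n_expert_raters,n_readers Panel sizes (defaults 5 and 10).
#' @param text,expert,reader Named lists overriding individual sub-parameters;
#'   see the source for the full set. Per-version vectors must match
#'   `length(versions)`.
#' @param seed Default seed used by the generators when no explicit seed is
#'   passed to them.
#' @return A list of class `icf_synth_config`.
#' @export
synth_config <- function(n_docs = 33,
                         versions = c("original", "chatgpt5", "grok4"),
                         n_expert_raters = 5, n_readers = 10,
                         text = list(), expert = list(), reader = list(),
                         seed = NULL) {
  nv <- length(versions)
  stretch <- function(x) if (length(x) == 1) rep(x, nv) else x
  text_defaults <- list(
    sentence_mean = c(37, 51, 65),
    words_per_sentence_mean = c(28, 20, 21),
    single_char_rate = c(0.88, 0.84, 0.80),
    polite_rate = c(0.08, 0.12, 0.12),
    harsh_rate = c(0.05, 0.05, 0.05),
    nesting_rate = c(0.32, 0.21, 0.23)
  )
  expert_defaults <- list(
    mu = rbind(
      existence = c(0.55, 0.64, 0.68),
      specificity = c(0.58, 0.83, 0.91),
      operability = c(1.14, 1.17, 1.18)
    ),
    # variance components calibrated analytically so the implied panel
    # reliability of rubric totals sits near ICC(2,k) ~ 0.83 for 5 raters
    sd_doc = 0.15, sd_rater = 0.15, sd_resid = 0.6
  )
  reader_defaults <- list(
    mu = rbind(
      comprehensibility = c(2.93, 3.76, 3.69),
      clarity = c(2.98, 3.78, 3.74),
      trustworthiness = c(3.30, 3.72, 3.61),
      friendliness = c(3.35, 3.75, 3.73),
      professionalism = c(3.25, 3.55, 3.64),
      acceptability = c(3.20, 3.77, 3.65)
    ),
    # calibrated so reader totals show moderate reliability,
    # ICC(2,k) ~ 0.59 for 10 raters
    sd_doc = 0.12, sd_rater = 0.65, sd_resid = 0.83
  )
  if (nv != 3) {
    # defaults above are for the 3-version design; recycle sensibly otherwise
    text_defaults <- lapply(text_defaults, function(x) rep(x[1], nv))
    expert_defaults$mu <- expert_defaults$mu[, rep(1, nv), drop = FALSE]
    reader_defaults$mu <- reader_defaults$mu[, rep(1, nv), drop = FALSE]
  }
  text <- utils::modifyList(text_defaults, text)
  text[names(text_defaults)] <- lapply(text[names(text_defaults)], stretch)
  expert <- utils::modifyList(expert_defaults, expert)
  reader <- utils::modifyList(reader_defaults, reader)
  expert$mu <- as.matrix(expert$mu)
  reader$mu <- as.matrix(reader$mu)
  if (is.null(rownames(expert$mu))) rownames(expert$mu) <- rownames(expert_defaults$mu)
  if (is.null(rownames(reader$mu))) rownames(reader$mu) <- rownames(reader_defaults$mu)

  rates <- c(text$polite_rate, text$harsh_rate, text$nesting_rate)
  if (any(rates < 0 | rates > 1)) {
    abort_config("injection and nesting rates must lie in [0, 1]")
  }
  sds <- c(expert$sd_doc, expert$sd_rater, expert$sd_resid,
           reader$sd_doc, reader$sd_rater, reader$sd_resid)
  if (any(sds < 0)) abort_config("standard deviations must be non-negative")
  if (n_docs < 1) abort_config("n_docs must be positive")
  bad_len <- vapply(text[names(text_defaults)], function(x) length(x) != nv, logical(1))
  if (any(bad_len) || ncol(expert$mu) != nv || ncol(reader$mu) != nv) {
    abort_config("per-version parameter vectors must match length(versions)")
  }

  structure(
    list(
      n_docs = as.integer(n_docs), versions = versions,
      n_expert_raters = as.integer(n_expert_raters),
      n_readers = as.integer(n_readers),
      text = text, expert = expert, reader = reader, seed = seed
    ),
    class = "icf_synth_config"
  )
}

# Synthetic vocabulary from disjoint CJK codepoint blocks. Every character
# belongs to exactly one word and lexicon-term characters appear nowhere
# else, so substring term counting cannot produce accidental matches and
# greedy longest-match segmentation recovers the generating word sequence
# exactly (all dictionary words are 1 or 2 characters; no single-character
# word starts a two-character dictionary entry).
synth_vocabulary <- function() {
  two_char <- vapply(seq_len(150), function(i) {
    intToUtf8(c(0x4E00 + 2 * (i - 1), 0x4E00 + 2 * (i - 1) + 1))
  }, character(1))
  one_char <- vapply(seq_len(60), function(i) intToUtf8(0x5300 + (i - 1)), character(1))
  polite <- vapply(seq_len(10), function(i) {
    intToUtf8(c(0x5400 + 2 * (i - 1), 0x5400 + 2 * (i - 1) + 1))
  }, character(1))
  harsh <- vapply(seq_len(10), function(i) {
    intToUtf8(c(0x5500 + 2 * (i - 1), 0x5500 + 2 * (i - 1) + 1))
  }, character(1))
  list(
    two_char = two_char, one_char = one_char,
    polite = polite, harsh = harsh,
    dictionary = c(two_char, one_char, polite, harsh)
  )
}

#' Generate a synthetic corpus with constructive ground truth
#'
#' Assembles documents sentence by sentence from the synthetic vocabulary:
#' sentence counts and words per sentence are Poisson draws around the
#' per-version means, polite/harsh lexicon terms are injected Bernoulli per
#' sentence at the configured rates (at most one of each per sentence, never
#' adjacent), and nested sentences receive a bracketed clause. All eight text
#' metrics are computed constructively from the generated word lists — not
#' via the metrics module — and returned as ground truth, which makes the
#' generator an independent oracle for [compute_text_metrics()].
#'
#' @param config An [synth_config()].
#' @param seed Integer seed (defaults to `config$seed`); fixing it fixes the
#'   corpus exactly.
#' @return A list: `corpus` (tibble `doc_id`, `version`, `text`), `truth`
#'   (tibble of the eight expected metrics per document version plus
#'   `n_polite`/`n_harsh`), `lexicon` (an [lexicon()]), `dictionary`
#'   (character vector for the greedy segmenter) and `text_config` (a ready
#'   [text_config()] whose segmenter uses that dictionary).
#' @export
generate_corpus <- function(config = synth_config(), seed = config$seed) {
  stopifnot(inherits(config, "icf_synth_config"))
  voc <- synth_vocabulary()
  lex <- lexicon(voc$polite, voc$harsh)
  tcfg <- text_config(segmenter = list(name = "greedy", dictionary = voc$dictionary))
  weights <- tcfg$leeyang$weights
  comma <- "，" # ideographic comma
  stop_mark <- "。" # ideographic full stop
  open_b <- "（" # fullwidth (
  close_b <- "）" # fullwidth )

  build <- function() {
    rows <- list()
    truths <- list()
    for (d in seq_len(config$n_docs)) {
      doc_id <- sprintf("doc%02d", d)
      for (vi in seq_along(config$versions)) {
        v <- config$versions[vi]
        n_sent <- max(3L, stats::rpois(1, config$text$sentence_mean[vi]))
        sent_texts <- character(n_sent)
        all_words <- list()
        n_polite <- 0L
        n_harsh <- 0L
        n_nested <- 0L
        for (s in seq_len(n_sent)) {
          n_words <- max(5L, stats::rpois(1, config$text$words_per_sentence_mean[vi]))
          singles <- stats::runif(n_words) < config$text$single_char_rate[vi]
          words <- ifelse(
            singles,
            sample(voc$one_char, n_words, replace = TRUE),
            sample(voc$two_char, n_words, replace = TRUE)
          )
          if (stats::runif(1) < config$text$polite_rate[vi]) {
            words[2] <- sample(voc$polite, 1)
            n_polite <- n_polite + 1L
          }
          if (stats::runif(1) < config$text$harsh_rate[vi]) {
            words[n_words - 1L] <- sample(voc$harsh, 1)
            n_harsh <- n_harsh + 1L
          }
          nested <- stats::runif(1) < config$text$nesting_rate[vi]
          rendered <- words
          if (nested) {
            rendered[3] <- paste0(open_b, rendered[3], close_b)
            n_nested <- n_nested + 1L
          } else if (stats::runif(1) < 0.5) {
            # a single internal comma: realistic, below the nesting threshold
            rendered[2] <- paste0(rendered[2], comma)
          }
          sent_texts[s] <- paste0(paste(rendered, collapse = ""), stop_mark)
          all_words[[s]] <- words
        }
        words_flat <- unlist(all_words, use.names = FALSE)
        wc <- length(words_flat)
        cc <- sum(nchar(words_flat))
        lex_pct <- 100 * mean(nchar(words_flat) >= 2)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          doc_id = doc_id, version = v,
          text = paste(sent_texts, collapse = "")
        )
        truths[[length(truths) + 1L]] <- tibble::tibble(
          doc_id = doc_id, version = v,
          character_count = cc, word_count = wc, sentence_count = n_sent,
          words_per_sentence = wc / n_sent, characters_per_word = cc / wc,
          nested_sentence_ratio = n_nested / n_sent,
          lee_yang_index = weights[["sentence"]] * (wc / n_sent) +
            weights[["word"]] * (cc / wc) + weights[["lex"]] * lex_pct,
          tone_friendliness =
            2.5 * (clamp((n_polite - n_harsh) / n_sent, -1, 1) + 1),
          n_polite = n_polite, n_harsh = n_harsh
        )
      }
    }
    list(corpus = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truths))
  }
  out <- with_seed_if(seed, build())
  c(out, list(lexicon = lex, dictionary = voc$dictionary, text_config = tcfg))
}

# Latent crossed-effects sampler shared by the score generators:
# value[rater, doc, version] = mu[version] + u_doc + v_rater + eps.
sample_latent <- function(n_docs, versions, n_raters, mu_version,
                          sd_doc, sd_rater, sd_resid, rater_prefix) {
  doc_ids <- sprintf("doc%02d", seq_len(n_docs))
  rater_ids <- sprintf("%s%02d", rater_prefix, seq_len(n_raters))
  u_doc <- stats::rnorm(n_docs, 0, sd_doc)
  v_rater <- stats::rnorm(n_raters, 0, sd_rater)
  grid <- tidyr::expand_grid(
    rater_id = rater_ids, doc_id = doc_ids, version = versions
  )
  vi <- match(grid$version, versions)
  grid$value <- mu_version[vi] +
    u_doc[match(grid$doc_id, doc_ids)] +
    v_rater[match(grid$rater_id, rater_ids)] +
    stats::rnorm(nrow(grid), 0, sd_resid)
  list(grid = grid, u_doc = stats::setNames(u_doc, doc_ids),
       v_rater = stats::setNames(v_rater, rater_ids))
}

#' Generate synthetic expert rubric scores
#'
#' Latent scores follow the crossed random-effects model the analysis layer
#' assumes: `mu(version, dimension) + u_doc + v_rater + eps` with one shared
#' document intercept and one shared rater intercept across indicators and
#' dimensions, and independent residual noise per cell. Latent values are
#' discretised by rounding and clamping to each dimension's range
#' (existence 0–1, specificity/operability 0–2) unless `continuous = TRUE`,
#' which returns the raw latent values so model-recovery checks can test the
#' fitter on the model it assumes, free of discretisation bias.
#'
#' @param config An [synth_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param continuous Skip discretisation.
#' @return A list: `records` (expert rubric tibble) and `truth` (generating
#'   parameters: `mu`, per-document and per-rater intercepts, SDs).
#' @export
generate_expert_scores <- function(config = synth_config(), seed = config$seed,
                                   continuous = FALSE) {
  stopifnot(inherits(config, "icf_synth_config"))
  p <- config$expert
  dims <- rownames(p$mu)
  bounds <- list(existence = c(0, 1), specificity = c(0, 2), operability = c(0, 2))
  build <- function() {
    base <- sample_latent(config$n_docs, config$versions, config$n_expert_raters,
                          rep(0, length(config$versions)),
                          p$sd_doc, p$sd_rater, 0, "expert")
    grid <- tidyr::expand_grid(
      rater_id = names(base$v_rater), doc_id = names(base$u_doc),
      version = config$versions, indicator_id = 1:20
    )
    vi <- match(grid$version, config$versions)
    shared <- base$u_doc[grid$doc_id] + base$v_rater[grid$rater_id]
    for (dim in dims) {
      latent <- p$mu[dim, vi] + shared + stats::rnorm(nrow(grid), 0, p$sd_resid)
      if (!continuous) {
        b <- bounds[[dim]]
        latent <- clamp(round(latent), b[1], b[2])
      }
      grid[[dim]] <- latent
    }
    list(
      records = grid,
      truth = list(mu = p$mu, u_doc = base$u_doc, v_rater = base$v_rater,
                   sd_doc = p$sd_doc, sd_rater = p$sd_rater,
                   sd_resid = p$sd_resid, continuous = continuous)
    )
  }
  with_seed_if(seed, build())
}

#' Generate synthetic reader comprehension scores
#'
#' Same crossed random-effects model as [generate_expert_scores()] with six
#' Likert dimensions, discretised by rounding and clamping to 1–5 unless
#' `continuous = TRUE`.
#'
#' @inheritParams generate_expert_scores
#' @return A list: `records` (reader scale tibble) and `truth`.
#' @export
generate_reader_scores <- function(config = synth_config(), seed = config$seed,
                                   continuous = FALSE) {
  stopifnot(inherits(config, "icf_synth_config"))
  p <- config$reader
  dims <- rownames(p$mu)
  build <- function() {
    base <- sample_latent(config$n_docs, config$versions, config$n_readers,
                          rep(0, length(config$versions)),
                          p$sd_doc, p$sd_rater, 0, "reader")
    grid <- base$grid[, c("rater_id", "doc_id", "version")]
    vi <- match(grid$version, config$versions)
    shared <- base$u_doc[grid$doc_id] + base$v_rater[grid$rater_id]
    for (dim in dims) {
      latent <- p$mu[dim, vi] + shared + stats::rnorm(nrow(grid), 0, p$sd_resid)
      if (!continuous) latent <- clamp(round(latent), 1, 5)
      grid[[dim]] <- latent
    }
    list(
      records = grid,
      truth = list(mu = p$mu, u_doc = base$u_doc, v_rater = base$v_rater,
                   sd_doc = p$sd_doc, sd_rater = p$sd_rater,
                   sd_resid = p$sd_resid, continuous = continuous)
    )
  }
  with_seed_if(seed, build())
}

#' Generate a continuous crossed-design score panel
#'
#' Draws one value per rater x document x version from
#' `baseline + effect[version] + u_doc + v_rater + eps` — the totals-scale
#' crossed design used for mixed-model parameter-recovery checks.
#'
#' @param n_docs,versions,n_raters Design size.
#' @param baseline Grand intercept.
#' @param effects Per-version fixed effects (same length as `versions`).
#' @param sd_doc,sd_rater,sd_resid Standard deviations of the document
#'   intercept, rater intercept and residual.
#' @param seed Integer seed.
#' @return A list: `data` (tibble `rater_id`, `doc_id`, `version`, `value`)
#'   and `truth` (the generating parameters and realised intercepts).
#' @export
generate_score_panel <- function(n_docs = 33,
                                 versions = c("original", "chatgpt5", "grok4"),
                                 n_raters = 5, baseline = 45,
                                 effects = c(0, 7, 10),
                                 sd_doc = 2, sd_rater = 1, sd_resid = 3,
                                 seed = NULL) {
  if (length(effects) != length(versions)) {
    abort_config("effects must match versions in length")
  }
  build <- function() {
    base <- sample_latent(n_docs, versions, n_raters,
                          baseline + effects, sd_doc, sd_rater, sd_resid,
                          "rater")
    list(
      data = base$grid,
      truth = list(baseline = baseline,
                   effects = stats::setNames(effects, versions),
                   u_doc = base$u_doc, v_rater = base$v_rater,
                   sd_doc = sd_doc, sd_rater = sd_rater, sd_resid = sd_resid)
    )
  }
  with_seed_if(seed, build())
}
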