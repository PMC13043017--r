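# Sentence splitting, segmentation and the eight per-document indicators.

test_that("sentences split on terminal punctuation, not on colons", {
  expect_length(split_sentences("今天咨询。请放心！"), 2)
  expect_equal(split_sentences("no terminal punctuation at all"),
               "no terminal punctuation at all")
  # the fullwidth colon is not a sentence delimiter
  s <- split_sentences("第一条：保密。第二条：例外。")
  expect_equal(s, c("第一条：保密。", "第二条：例外。"))
  # delimiter runs stay attached to the preceding sentence
  expect_equal(split_sentences("真的吗？！好。"), c("真的吗？！", "好。"))
  # hard newlines split even without punctuation
  expect_length(split_sentences("line one\nline two"), 2)
  expect_error(split_sentences("   "), class = "icfeval_degenerate_error")
})

test_that("word segmentation honours the pluggable contract", {
  ws <- segmenter_whitespace()
  expect_equal(segment_words("please help", ws), c("please", "help"))
  expect_equal(segment_words("，。！", ws), character(0))

  greedy <- segmenter_greedy(c("心理", "咨询"))
  expect_equal(segment_words("心理咨询", greedy), c("心理", "咨询"))
  # greedy prefers the longest match and falls back to single characters
  greedy2 <- segmenter_greedy(c("心理", "心", "理咨", "询"))
  expect_equal(segment_words("心理咨询", greedy2), c("心理", "咨", "询"))
})

test_that("structural features follow their defining arithmetic", {
  toks <- tokens_from_words(list(c("a", "b", "c", "d"), c("e", "f", "g", "h", "i", "j")))
  s <- compute_structural(toks)
  expect_equal(s$word_count, 10)
  expect_equal(s$sentence_count, 2)
  expect_equal(s$words_per_sentence, 5)
  expect_equal(s$characters_per_word, 1)

  toks2 <- tokens_from_words(list(c("心理", "咨询", "师")))
  s2 <- compute_structural(toks2)
  expect_equal(s2$character_count, 5)
  expect_equal(s2$characters_per_word, 5 / 3)
})

test_that("nested sentence ratio applies the marker/separator rule", {
  wcfg <- text_config(segmenter = list(name = "whitespace"))
  expect_equal(nested_sentence_ratio(tokenize_document("简单 句。又 一 句。", wcfg)), 0)
  expect_equal(
    nested_sentence_ratio(tokenize_document("他说（注释）了。另（备注）句。", wcfg)), 1
  )
  # 4 sentences, exactly one with three internal commas, threshold 3
  text <- "甲，乙，丙，丁。简单句。又一句。再一句。"
  expect_equal(nested_sentence_ratio(tokenize_document(text, wcfg)), 0.25)
  # an unmatched opening bracket does not count as a paired marker
  expect_equal(nested_sentence_ratio(tokenize_document("他说（注释了。", wcfg)), 0)
})

test_that("Lee-Yang index is the stated weighted composite", {
  # 1 sentence, 5 words, 6 characters, 20% of words with >= 2 characters:
  # components are (5, 1.2, 20), so unit weights give their plain sum
  toks <- tokens_from_words(list(c("aa", "b", "c", "d", "e")))
  expect_equal(lee_yang_index(toks, c(sentence = 1, word = 1, lex = 1)),
               5 + 1.2 + 20)
  # with w_lex = 0, doubling sentence length doubles the first term exactly
  toks2 <- tokens_from_words(list(rep("a", 10)))
  toks1 <- tokens_from_words(list(rep("a", 5)))
  w <- c(sentence = 2, word = 0, lex = 0)
  expect_equal(lee_yang_index(toks2, w), 2 * lee_yang_index(toks1, w))
  # longer sentences -> strictly larger index under positive weights
  expect_gt(
    lee_yang_index(tokens_from_words(list(rep("a", 8))), c(1, 1, 1)),
    lee_yang_index(tokens_from_words(list(rep("a", 4))), c(1, 1, 1))
  )
  expect_error(lee_yang_index(toks, c(0, 0, 0)), class = "icfeval_config_error")
})

test_that("tone friendliness follows the clamped linear map", {
  wcfg <- text_config(segmenter = list(name = "whitespace"))
  lex <- lexicon(polite = c("请", "感谢"), harsh = c("必须", "禁止"))
  # equal counts (here zero of each) give the 2.5 midpoint
  expect_equal(tone_friendliness(tokenize_document("中性 句子。", wcfg), lex), 2.5)
  expect_equal(
    tone_friendliness(tokenize_document("请 必须 来。", wcfg), lex), 2.5
  )
  # 10 sentences, 5 polite, 0 harsh -> raw 0.5 -> 3.75
  text <- paste0(c(rep("请 来。", 5), rep("空 句。", 5)), collapse = "")
  expect_equal(tone_friendliness(tokenize_document(text, wcfg), lex), 3.75)
  # 1 sentence with 3 harsh terms -> raw -3 clamped to -1 -> 0
  expect_equal(
    tone_friendliness(tokenize_document("必须 禁止 必须。", wcfg), lex), 0
  )
  # overlapping matches are not double counted; longer terms win
  lex2 <- lexicon(polite = c("abc", "cd"), harsh = "zz")
  expect_equal(
    tone_friendliness(tokenize_document("abcd.", wcfg), lex2), 5
  ) # one match ("abc"), not two
})

test_that("tone is monotone in term counts and always within [0, 5]", {
  wcfg <- text_config(segmenter = list(name = "whitespace"))
  lex <- lexicon(polite = "好", harsh = "坏")
  for (n_h in 0:3) {
    scores <- vapply(0:6, function(n_p) {
      text <- paste0(
        paste(c(rep("好", n_p), rep("坏", n_h), "空"), collapse = " "),
        "。另 句。另 句。"
      )
      tone_friendliness(tokenize_document(text, wcfg), lex)
    }, numeric(1))
    expect_true(all(diff(scores) >= 0)) # non-decreasing in polite count
    expect_true(all(scores >= 0 & scores <= 5))
  }
})

test_that("self-concatenation doubles counts and preserves every ratio metric", {
  gen <- generate_corpus(synth_config(n_docs = 2), seed = 5)
  lex <- gen$lexicon
  cfg <- gen$text_config
  for (i in seq_len(nrow(gen$corpus))) {
    one <- gen$corpus[i, ]
    two <- one
    two$text <- paste0(one$text, one$text)
    m1 <- compute_text_metrics(one, lex, cfg)
    m2 <- compute_text_metrics(two, lex, cfg)
    for (col in c("character_count", "word_count", "sentence_count")) {
      expect_equal(m2[[col]], 2 * m1[[col]])
    }
    for (col in c("words_per_sentence", "characters_per_word",
                  "nested_sentence_ratio", "lee_yang_index", "tone_friendliness")) {
      expect_equal(m2[[col]], m1[[col]])
    }
  }
})

test_that("the metric table is deterministic and document-order invariant", {
  gen <- generate_corpus(synth_config(n_docs = 3), seed = 9)
  m1 <- compute_text_metrics(gen$corpus, gen$lexicon, gen$text_config)
  m2 <- compute_text_metrics(gen$corpus, gen$lexicon, gen$text_config)
  expect_identical(m1, m2)
  shuffled <- gen$corpus[rev(seq_len(nrow(gen$corpus))), ]
  m3 <- compute_text_metrics(shuffled, gen$lexicon, gen$text_config)
  expect_equal(
    dplyr::arrange(m3, doc_id, version),
    dplyr::arrange(m1, doc_id, version)
  )
})
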