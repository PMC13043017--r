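# Independent oracles and fixture builders used across the suite. Each oracle
# is deliberately written as plainly as possible (enumeration / brute force /
# textbook formulas) and shares no code with the implementation it checks.

# Exact two-sided signed-rank p-value by enumerating all 2^n sign assignments
# of the ranked absolute differences (zero differences discarded first).
wilcoxon_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  v_all <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  list(statistic = v_obs, p = p, n = n)
}

# Brute-force Benjamini-Hochberg step-up: for each p_i the minimum over all
# thresholds j >= rank(i) of p_(j) * n / j, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(sorted[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Two-way ANOVA mean squares from stats::aov, plugged into the textbook
# average-measures absolute-agreement ICC expression.
icc2k_aov_oracle <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  df <- data.frame(
    y = as.vector(mat),
    target = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ target + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  list(
    icc2k = (msr - mse) / (msr + (msc - mse) / n),
    icc21 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    msr = msr, msc = msc, mse = mse
  )
}

# Full expert-rubric grid with constant dimension scores.
make_expert_records <- function(raters = 2, docs = c("docA", "docB"),
                                versions = c("original", "chatgpt5", "grok4"),
                                existence = 1, specificity = 2, operability = 2) {
  grid <- expand.grid(
    rater_id = sprintf("expert%02d", seq_len(raters)),
    doc_id = docs, version = versions, indicator_id = 1:20,
    stringsAsFactors = FALSE
  )
  grid$existence <- existence
  grid$specificity <- specificity
  grid$operability <- operability
  tibble::as_tibble(grid)
}

# Full reader-scale grid with a constant Likert score.
make_reader_records <- function(raters = 2, docs = c("docA", "docB"),
                                versions = c("original", "chatgpt5", "grok4"),
                                score = 3) {
  grid <- expand.grid(
    rater_id = sprintf("reader%02d", seq_len(raters)),
    doc_id = docs, version = versions,
    stringsAsFactors = FALSE
  )
  for (dim in c("comprehensibility", "clarity", "trustworthiness",
                "friendliness", "professionalism", "acceptability")) {
    grid[[dim]] <- score
  }
  tibble::as_tibble(grid)
}

# A tokenized document built directly from word lists (whitespace pipeline).
tokens_from_words <- function(words_per_sentence) {
  text <- paste(vapply(words_per_sentence, paste, character(1), collapse = " "),
                collapse = ". ")
  tokenize_document(paste0(text, "."),
                    text_config(segmenter = list(name = "whitespace")))
}

# Write a small corpus (manifest + text files) into a temp dir; returns the
# manifest path.
write_tmp_corpus <- function(docs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  icfeval::write_corpus(docs, dir)
}
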