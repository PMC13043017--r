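# icfeval

Multidimensional evaluation of informed consent forms (ICFs) for
psychological counseling services, for researchers and service providers who
need to compare document versions — for example originals against rewritten
or LLM-optimized drafts — on more than gut feeling.

The package evaluates each document version on three dimensions and then
tests version differences with the statistics appropriate for small crossed
rater panels:

1. **Text structure and readability** (Chinese text): character count, word
   count, sentence count, words per sentence, characters per word, nested
   sentence ratio, the Lee-Yang readability composite
   `LY = w_s·(words/sentence) + w_w·(chars/word) + w_x·(% words ≥ 2 chars)`,
   and a lexicon-based tone-friendliness score
   `tone = 2.5·(clamp((n_p − n_h)/S, −1, 1) + 1)` on a 0–5 scale, where
   `n_p`/`n_h` count polite and harsh dictionary terms and `S` is the
   sentence count.
2. **Expert content quality**: a 20-indicator rubric (confidentiality,
   exceptions to confidentiality, client rights, …, target population), each
   indicator scored on existence (0–1), specificity (0–2) and operability
   (0–2) — subtotals 20/40/40, total 100. Rater scores are summed within
   rater, then averaged across raters per document version.
3. **Reader comprehension**: six 1–5 Likert dimensions (comprehensibility,
   clarity, trustworthiness, friendliness, professionalism, acceptability);
   totals span 6–30, dimension means rescale to 1–5.

The statistical layer provides paired Wilcoxon signed-rank tests (exact for
small untied samples) with effect sizes `r = |z|/√n` and Benjamini–Hochberg
FDR adjustment, panel reliability as Shrout–Fleiss ICC(2,k), and crossed
random-intercept linear mixed models
`value ~ version + (1|doc_id) + (1|rater_id)` fitted by REML with Wald
inference. A synthetic generator reproduces the full study design (33
documents × 3 versions, 5 experts, 10 readers) with exactly known ground
truth, so the entire pipeline is testable without any external data.

## Worked example

Run the whole pipeline on a seeded synthetic study and look at three of its
sections:

```r
library(icfeval)
report <- run_pipeline(list(synthetic = TRUE, seed = 42))

dplyr::filter(report$metrics$summary,
              outcome %in% c("words_per_sentence", "lee_yang_index", "tone_friendliness"))
#>    version            outcome   mean     sd
#>  chatgpt5 words_per_sentence 19.989 0.5313
#>  chatgpt5     lee_yang_index 33.335 0.5420
#>  chatgpt5  tone_friendliness  2.669 0.1363
#>     grok4 words_per_sentence 20.960 0.6252
#>     grok4     lee_yang_index 35.103 0.6531
#>     grok4  tone_friendliness  2.721 0.1041
#>  original words_per_sentence 27.952 0.8775
#>  original     lee_yang_index 40.464 0.9327
#>  original  tone_friendliness  2.582 0.1489
```

Original documents have markedly longer sentences, a higher (harder)
readability index and slightly less friendly tone than either rewritten
version — by construction of the generator, which plants those differences.

```r
report$quality$comparisons[report$quality$comparisons$outcome == "total",
                           c("pair", "n", "z", "p_fdr", "effect_r")]
#>                  pair  n    z    p_fdr effect_r
#>  chatgpt5 vs original 32 4.93 2.49e-06    0.871
#>     grok4 vs original 33 5.00 2.25e-06    0.871
#>     grok4 vs chatgpt5 33 3.06 3.27e-03    0.534
```

Paired signed-rank tests on the rubric totals (FDR-adjusted within the
block): both rewritten versions beat the originals with large effect sizes,
and the two rewrites differ more modestly. One pair has `n = 32` because a
document with a zero difference is discarded under the default zero rule.

```r
report$quality$icc[, 1:6]
#>      form value ci_low ci_high k n_targets
#>  ICC(2,k) 0.763  0.394   0.888 5        99

report$quality$lmm_contrasts[report$quality$lmm_contrasts$outcome == "total",
                             c("contrast", "beta", "se", "ci_low", "ci_high", "p")]
#>              contrast beta    se ci_low ci_high        p
#>  chatgpt5 vs original 5.73 0.504  4.739    6.72 6.56e-30
#>     grok4 vs original 7.38 0.504  6.394    8.37 1.50e-48
#>     grok4 vs chatgpt5 1.65 0.504  0.666    2.64 1.03e-03
```

The 5-expert panel mean is reliable (ICC(2,k) = 0.76 over 99 evaluation
units), and the mixed model — which accounts for document and rater
intercepts — estimates the version effects on the 0–100 quality scale with
a single shared SE thanks to the balanced crossed design.

Real data enter through the same surfaces: `read_corpus()` (a
`doc_id,version,path` manifest of UTF-8 text files), `read_lexicon()` (one
term per line) and `read_score_table()` (long-format CSV per schema). A
thin command-line wrapper with `simulate / metrics / aggregate / compare /
icc / lmm / run` subcommands lives at `inst/cli/icfeval.R`.

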