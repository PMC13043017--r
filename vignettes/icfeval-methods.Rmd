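---
title: "Evaluating counseling consent documents: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating counseling consent documents: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icfeval)
```

## The problem

Informed consent forms (ICFs) for psychological counseling vary widely in
structure, completeness and language. Evaluating them — and evaluating
attempts to rewrite them, whether by humans or by language models — requires
three distinct lenses: how the text is built (structure and readability),
whether the professionally required content is present and usable (expert
content quality), and whether an actual client can read and accept it
(reader comprehension). `icfeval` implements all three as a reproducible
pipeline for Chinese-language documents, together with the statistical layer
needed to compare document versions scored by small rater panels.

The package operates on a *corpus*: a set of document identifiers, each
available in several *versions* (by default `original`, `chatgpt5`, `grok4`,
but the version set is configuration). Scores arrive in long format, one row
per rater and evaluation unit, because that is the shape the mixed models
consume.

## Text structure and readability

Eight indicators are computed per document version through one standardized
pipeline: sentence splitting, word segmentation, then the metrics.

**Sentence splitting.** No universal definition of a Chinese sentence
boundary exists, so the delimiter set is configuration. The default is the
terminal punctuation 。！？…； with ASCII `. ! ? ;`, plus hard newlines;
delimiter runs stay attached to the preceding sentence; text with no
delimiter is one sentence. These choices matter because three of the eight
metrics are normalised by sentence count.

**Word segmentation** is a pluggable contract (`character(1)` run in, word
vector out). Two implementations ship: greedy longest-match against a user
dictionary (the classic baseline for unspaced text) and whitespace splitting
for pre-segmented text. Segmenter choice changes word counts; isolating it
behind a contract keeps everything downstream reproducible once the
segmenter is pinned. Punctuation, symbols and whitespace are never part of
words, and `character_count` counts word characters only, which keeps
`characters_per_word = character_count / word_count` exactly
self-consistent.

**Nested sentence ratio.** Embedded-clause detection without a parser is
necessarily an operationalisation. The shipped classifier marks a sentence
as nested when it contains a paired embedding marker (an opening
bracket/quote with its closing partner after it) or at least
`separator_threshold` (default 3) internal clause separators (，、：,).
Both lists and the threshold are configuration; the classifier is documented
as a proxy, not a syntactic ground truth.

**Lee-Yang readability index.** A weighted composite, higher = harder:

$$LY = w_s \cdot \overline{\text{words/sentence}} + w_w \cdot
\overline{\text{chars/word}} + w_x \cdot X,$$

where $X$ is the percentage (0–100) of words with at least two characters
(the lexical-complexity proportion). Published applications of this index do
not always print the weight constants, so the weights are explicit
configuration. The default `(1, 10, 0.1)` puts the three components on
comparable scales for typical consent-form text (roughly 20–30, 11–12 and
2–9 respectively); reproducing any specific published calibration requires
supplying its weights — the default is *not* expected to match published
corpus means numerically.

**Tone friendliness.** A surface-level lexical proxy on a 0–5 scale. Given
disjoint polite/empathy and harsh term lists, with per-document counts
$n_p$ and $n_h$ and sentence count $S$:

$$\text{tone} = 2.5\,(\mathrm{clamp}((n_p - n_h)/S,\,-1,\,1) + 1).$$

Equal counts give the midpoint 2.5; the normalised difference is truncated
at ±1 before mapping (equivalently, the score is clipped to [0, 5]). Terms
are counted by raw substring matching per sentence — longer terms first,
overlapping matches never double-counted — so the score is independent of
the segmenter dialect. Disjointness of the two lists is enforced as an
error: a term in both lists would make the score's sign ambiguous. The
score measures lexical surface tone only; it is blind to pragmatics (e.g.
legally protective wording that is strict but ethically appropriate).

## The content-quality rubric and comprehension scale

The expert rubric covers 20 core indicators (confidentiality, exceptions to
confidentiality, client rights, …, target population; the machine-readable
codebook ships in `inst/extdata/codebook.csv`). Each indicator is scored on
**existence** (0–1: presented as an independent item), **specificity** (0–2:
concrete detail) and **operability** (0–2: actionable procedure) — 5 points
per indicator, dimension subscores of 20/40/40, total 100. An element
mentioned only inside another section scores existence 0 while specificity
and operability are still assessed, so `existence = 0` with positive content
scores is a *valid* record, and validation treats it as such.

The comprehension scale has six 1–5 Likert dimensions (comprehensibility,
clarity, trustworthiness, friendliness, professionalism, acceptability);
totals span 6–30 and `dimension_means = total/6` rescales back to 1–5.

Aggregation order is fixed: sum within rater (rubric) or take raw ratings
(scale), then average across raters per document version. Nothing is ever
rounded, and missing cells are never imputed — incomplete data blocks
aggregation unless `allow_partial = TRUE`, in which case an incomplete
rater is dropped for that document (dropped, not rescaled: rescaling a
partial rubric total would silently change what the subtotals mean).
Per-rater aggregates (`by_rater = TRUE`) are retained because the
reliability and mixed-model layers need them.

## Statistical comparison layer

**Paired Wilcoxon signed-rank** (`wilcoxon_paired()`): two-sided; zero
differences are discarded by default (the original signed-rank rule), with
the Pratt variant available by flag since the conventional choice is not
universal. With ≤ 25 usable pairs and untied absolute differences the exact
null distribution is used (`psignrank`); otherwise the normal approximation
with continuity and tie correction. The effect size is $r = |z|/\sqrt{n}$
over non-zero pairs; on the exact branch $z$ is back-computed from the exact
p so $r$ remains defined. The test suite checks the exact branch against
full $2^n$ sign enumeration and the approximate branch against the reference
implementation in base R.

**Benjamini–Hochberg FDR** (`bh_fdr()`): classic step-up with monotonicity
enforcement. Which tests form one multiplicity family is a configuration
decision (`fdr_family`): the default `"block"` adjusts all comparisons
produced by one `compare_versions()` call together (e.g. 8 text metrics × 3
version pairs = 24 tests); `"outcome"` and `"pair"` are available because
the right family depends on the claim being made, which the data cannot
decide.

**ICC(2,k)** (`icc2k()`): two-way random effects, average measures,
absolute agreement — the reliability of the *panel mean*. Computed from the
two-way ANOVA mean squares,
$\mathrm{ICC}(2,k) = (MS_R - MS_E)/(MS_R + (MS_C - MS_E)/n)$,
with the standard F-based interval for the single-measure form stepped up
by Spearman–Brown. Missing cells are an error (no imputation); a constant
panel (zero between-target variance) is a degenerate-input error rather
than a silent 0/0. With perfect agreement the interval collapses to the
point value 1.

**Crossed random-intercept LMM** (`fit_lmm()`): `value ~ version +
(1|doc_id) + (1|rater_id)`, REML via `lme4`, the standard model when every
rater scores every document version. Inference is Wald-z with
`beta ± 1.96·se` intervals — the conventional default when no degrees-of-
freedom correction is specified. All pairwise version contrasts come from a
single fit by linear combination of coefficients, so they are exactly
consistent under reference-level changes. A marginal optimizer
gradient-check failure triggers one refit with `bobyqa` before an error is
raised; singular fits are flagged, not raised, because boundary variance
estimates are legitimate outcomes. Mixed-model p-values are reported
unadjusted; the FDR layer applies to the Wilcoxon family only.

## The synthetic study generator

`synth_config()` encodes the reference design: 33 documents × 3 versions,
5 experts × 20 indicators × 3 dimensions, 10 readers × 6 dimensions.

*Text.* Documents are assembled from a synthetic vocabulary in disjoint CJK
codepoint blocks (two-character words, single-character words, polite terms,
harsh terms). Because every character belongs to exactly one dictionary
word and lexicon characters appear nowhere else, greedy segmentation
provably recovers the generating word sequence and substring term counting
cannot produce accidental matches — which is what lets the generator return
*constructive* ground truth for all eight metrics (computed from its own
word lists, not by calling the metrics module). Per-version parameters
(mean sentence counts 37/51/65, words per sentence 28/20/21, nesting rates
0.32/0.21/0.23, single-character share tuned to give ~1.1–1.2 characters
per word, polite-injection rates 0.08/0.12/0.12 against a constant harsh
rate 0.05) reproduce the magnitudes observed in real counseling-ICF
corpora, including expected tone scores near 2.57/2.67/2.67.

*Scores.* Latent cell values follow exactly the model the analysis layer
assumes: $\mu(\text{version, dimension}) + u_{doc} + v_{rater} +
\varepsilon$, with one shared document intercept and one shared rater
intercept. Per-dimension means are set to the per-indicator magnitudes of
real corpora (e.g. rubric totals near 45/53/55 and comprehension totals
near 19/22/22 across the three versions). Variance components were
calibrated once, analytically: writing a rubric total as
$60 u_{doc} + 60 v_{rater} + \sum_{1}^{60}\varepsilon$ and a reader total as
the analogous 6-cell sum, the SDs were solved so the implied panel
reliability of totals sits near ICC(2,k) ≈ 0.83 for the 5-expert panel and
≈ 0.59 for the 10-reader panel — giving (0.15, 0.15, 0.6) for experts and
(0.12, 0.65, 0.83) for readers on the cell scale. The calibration is done
on the continuous latent scale; discretisation (round then clamp to each
dimension's range — monotone and simple) shifts realised means and
reliabilities somewhat, typically compressing rubric totals downward and
raising the expert ICC. `continuous = TRUE` skips discretisation so that
mixed-model recovery is tested on the model the fitter actually assumes,
separating fitter correctness from discretisation bias.
`generate_score_panel()` generates directly on the totals scale (defaults:
document SD 2, rater SD 1, residual SD 3, version effects 0/+7/+10) for
parameter-recovery studies.

*What passing tests do and do not show.* The generator matches the
assumed statistical structure by construction; real documents are not bags
of dictionary words, real raters are not exchangeable Gaussians, and real
rubric scores are not rounded latent normals. Green tests certify the
pipeline's arithmetic, its oracles and its estimator behaviour under the
assumed model — not that the model describes any particular real corpus.

## Problem sizes and numerical choices

The test suite and the acceptance script use: full $2^n$ enumeration up to
$n = 12$ for the signed-rank oracle; brute-force step-up on p-vectors up to
length 8; generator cross-validation on 102 document versions (integer
metrics exact, ratio metrics to 1e-9); and 20 replicates of the
33 × 3 × 5 recovery design (mean contrast within ±0.5 of truth, ≥ 17/20
interval coverage). Ties in the Wilcoxon statistic fall back to the
corrected normal approximation; equal version vectors yield a flagged
degenerate row rather than an error so one constant outcome cannot abort a
whole comparison table. Reports serialise with full numeric precision so a
JSON round-trip reproduces every value exactly.

## Known limitations

* The Lee-Yang weights default is a scale-matching choice, not the original
  published calibration; absolute index values are only comparable within a
  fixed configuration.
* The nested-sentence classifier is a declared proxy (markers/separators),
  not a parse.
* Tone friendliness is lexical surface tone; it can misread legally
  protective or pragmatically appropriate strict wording.
* The rubric is validated and aggregated, never auto-scored: scoring
  documents against the 20 indicators remains human work.
* Likert sums are treated as continuous outcomes in the mixed models
  (conventional in this literature); ordinal models are out of scope.
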