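Package: icfeval
Title: Multidimensional Evaluation of Counseling Informed Consent Documents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating informed consent forms (ICFs) for
    psychological counseling services across three dimensions: textual
    structure and readability of Chinese documents (structural counts,
    nested sentence ratio, Lee-Yang readability composite, and a
    lexicon-based tone-friendliness score), an expert content-quality
    rubric of 20 indicators scored on existence, specificity and
    operability, and a six-dimension client reading-comprehension scale.
    Includes the statistical comparison layer used to contrast document
    versions (paired Wilcoxon signed-rank tests with Benjamini-Hochberg
    false discovery rate adjustment and effect sizes, intraclass
    correlation ICC(2,k) for rater panels, and crossed random-intercept
    linear mixed models), and a synthetic corpus and rater-score
    generator with constructive ground truth so the full pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
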