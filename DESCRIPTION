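Package: scireadability
Title: Readability Trends in Scientific Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the readability of scientific abstracts and its
    change over time. Implements rule-based cleaning and sentence segmentation
    of abstract text, a three-step syllable counter backed by a bundled
    exception dictionary, the Flesch Reading Ease and New Dale-Chall
    readability formulas, corpus-derived science-specific common-word and
    jargon lists with verification overlap, yearly trend summaries with
    Pearson correlations, and a ladder of linear mixed-effects models (journal
    random intercepts and slopes) with AIC/BIC comparison and author-count
    covariates. A synthetic abstract-corpus generator with closed-form ground
    truth makes every pipeline stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
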