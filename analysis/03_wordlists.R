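#!/usr/bin/env Rscript
# Step 3: derive a science-specific common-word list from the corpus, check
# it against an independently derived verification list, and trace how
# word-list coverage of abstracts shifts over the years.

suppressMessages(library(scireadability))

records <- read_abstract_records("results/corpus.tsv", format = "table")

strata <- list(c(1976, 1989), c(1990, 2002), c(2003, 2015))
dcfg <- derivation_config(strata = strata, n_per_stratum = 400L, k = 150L,
                          seed = 11L)
derived <- derive_science_common_words(records, dcfg)
write_word_list(derived, "results/science_common_derived.txt")
write_derivation_report(derived, "results/derivation_report.json")

# verification: same procedure on an independent corpus from the same
# generative conditions
ver_records <- generate_corpus(generator_config(seed = 2L))$records
verification <- derive_science_common_words(ver_records, dcfg)
overlap <- verification_overlap(derived, verification)

# documents used in the derivation are excluded from downstream analysis
used <- attr(derived, "derivation_report")$sampled_doc_ids
kept <- records[!(records$doc_id %in% used), ]

common_cov <- yearly_coverage(kept, ndc_common_words())
jargon_cov <- yearly_coverage(kept, science_jargon_words())
derived_cov <- yearly_coverage(kept, derived)
cov <- dplyr::bind_rows(
  common = common_cov, jargon = jargon_cov, derived = derived_cov,
  .id = "list"
)
readr::write_tsv(cov, "results/yearly_coverage.tsv")

wft <- word_frequency_trend(kept, "furthermore")
readr::write_tsv(wft, "results/word_trend_furthermore.tsv")

write_manifest(
  run_manifest(
    "derive-wordlist",
    inputs = c(corpus = "results/corpus.tsv"),
    outputs = c(list = "results/science_common_derived.txt",
                report = "results/derivation_report.json",
                coverage = "results/yearly_coverage.tsv"),
    seed = dcfg$seed,
    counts = list(sampled = length(used), remaining = nrow(kept)),
    params = list(k = dcfg$k, n_per_stratum = dcfg$n_per_stratum)
  ),
  "results/03_manifest.json"
)

cat(sprintf("derived %d words; verification overlap %.1f%%\n",
            length(derived$words), 100 * overlap))
cat(sprintf("coverage trend r: common %+.3f, derived %+.3f\n",
            pearson_trend(common_cov$year, common_cov$mean_coverage)$r,
            pearson_trend(derived_cov$year, derived_cov$mean_coverage)$r))
cat(sprintf("'furthermore' frequency trend r: %+.3f\n",
            pearson_trend(wft$year, wft$mean_pct)$r))
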