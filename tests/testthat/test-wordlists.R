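# a toy corpus whose token frequencies are known exactly: text is already
# clean, so the full token stream can be enumerated by hand or brute force
toy_corpus <- function() {
  make_records(
    c("zeta zeta zeta beta. beta alpha gamma delta.",
      "zeta zeta beta alpha. gamma gamma epsilon zeta.",
      "alpha beta delta zeta. epsilon gamma delta zeta."),
    years = c(1965, 1975, 1985)
  )
}

toy_cfg <- function(k, exclusion = word_list(character(0)), seed = 1L,
                    n_per_stratum = 1L) {
  derivation_config(
    strata = list(c(1960, 1969), c(1970, 1979), c(1980, 1989)),
    n_per_stratum = n_per_stratum, k = k, exclusion = exclusion, seed = seed
  )
}

test_that("derivation equals the brute-force frequency oracle", {
  recs <- toy_corpus()
  toks <- unlist(strsplit(gsub("\\.", "", recs$text), "\\s+"))
  for (k in c(1L, 5L)) {
    wl <- derive_science_common_words(recs, toy_cfg(k))
    expect_equal(wl$words, rank_words_oracle(toks, k = k), label = paste0("k=", k))
  }
  # full vocabulary, with a warning for over-large k
  expect_warning(full <- derive_science_common_words(recs, toy_cfg(99L)),
                 "exceeds available vocabulary")
  expect_equal(full$words, rank_words_oracle(toks, k = 99L))
})

test_that("exclusion lists shift the ranking to the next words", {
  recs <- toy_corpus()
  toks <- unlist(strsplit(gsub("\\.", "", recs$text), "\\s+"))
  excl <- word_list(c("zeta", "beta"))
  wl <- derive_science_common_words(recs, toy_cfg(3L, exclusion = excl))
  expect_equal(wl$words, rank_words_oracle(toks, exclusion = excl$words, k = 3L))
  expect_false(any(c("zeta", "beta") %in% wl$words))
})

test_that("frequency ties break alphabetically", {
  recs <- make_records(c("mango mango apple. kiwi kiwi banana."),
                       years = 1965)
  cfg <- derivation_config(strata = list(c(1960, 1969)), n_per_stratum = 1L,
                           k = 3L, exclusion = word_list(character(0)))
  wl <- derive_science_common_words(recs, cfg)
  expect_equal(wl$words, c("kiwi", "mango", "apple"))
})

test_that("derivation is deterministic under the seed and records its sample", {
  gen <- generate_corpus(small_config(seed = 3L))
  cfg <- derivation_config(strata = list(c(1990, 1999), c(2000, 2009)),
                           n_per_stratum = 50L, k = 40L, seed = 9L)
  a <- derive_science_common_words(gen$records, cfg)
  b <- derive_science_common_words(gen$records, cfg)
  expect_identical(a$words, b$words)
  rep <- attr(a, "derivation_report")
  expect_length(rep$sampled_doc_ids, 100L)
  expect_identical(rep, attr(b, "derivation_report"))
})

test_that("an undersized stratum is reported by name", {
  recs <- toy_corpus()
  cfg <- derivation_config(strata = list(c(1960, 1969), c(1990, 1999)),
                           n_per_stratum = 1L, k = 2L,
                           exclusion = word_list(character(0)))
  expect_error(derive_science_common_words(recs, cfg), "1990-1999")
})

test_that("verification overlap is an intersection fraction", {
  a <- word_list(c("alpha", "beta", "gamma", "delta"))
  expect_equal(verification_overlap(a, a), 1.0)
  expect_equal(verification_overlap(a, word_list(c("x", "y"))), 0.0)
  b <- word_list(c("alpha", "beta", "gamma", "omega"))
  expect_equal(verification_overlap(a, b), 0.75)
  expect_error(verification_overlap(word_list(character(0)), a), "empty")
})

test_that("list coverage is token-level and spans its extremes", {
  tok <- segment("the cat sat. it purred loudly.")
  all_list <- word_list(c("the", "cat", "sat", "it", "purred", "loudly"))
  expect_equal(list_coverage(tok, all_list), 100.0)
  expect_equal(list_coverage(tok, word_list("nothing")), 0.0)
  two_of_six <- word_list(c("cat", "purred"))
  expect_equal(list_coverage(tok, two_of_six), 100 * 2 / 6, tolerance = 1e-12)
  empty <- segment("brr grr.")
  expect_warning(cov <- list_coverage(empty, all_list), "no tokens")
  expect_true(is.na(cov))
})

test_that("coverage of complementary lists partitioning the vocabulary sums to 100", {
  gen <- generate_corpus(small_config(n_abstracts = 40L, seed = 21L))
  cfg <- small_config()
  part_a <- cfg$easy_vocab
  part_b <- cfg$jargon_vocab
  for (i in c(1L, 17L, 40L)) {
    tok <- segment(clean_text(gen$records$text[i]), gen$records$doc_id[i])
    expect_equal(list_coverage(tok, part_a) + list_coverage(tok, part_b),
                 100, tolerance = 1e-9)
  }
})

test_that("word frequency trends track the generator", {
  # a five-word jargon vocabulary makes each word's share large enough for
  # its yearly trend to dominate sampling noise
  jargon <- word_list(c("bantorine", "ferlodium", "morantical",
                        "pelagosite", "vendurial"))
  easy <- word_list(c("bam", "bem", "bim", "bom", "bum"))
  cfg <- small_config(n_abstracts = 1200L, seed = 13L,
                      easy_vocab = easy, jargon_vocab = jargon,
                      jargon_weight_base = 0.2, jargon_weight_slope = 0.005,
                      author_effect = 0)
  gen <- generate_corpus(cfg)
  tr <- word_frequency_trend(gen$records, "bantorine")
  expect_true(all(tr$n_abstracts >= 10L))
  # rising jargon weight implies a rising frequency for a jargon word
  expect_gt(stats::coef(stats::lm(mean_pct ~ year, data = tr))["year"], 0)

  flat <- word_frequency_trend(gen$records, "notawordanywhere")
  expect_true(all(flat$mean_pct == 0))

  single <- make_records(rep("the cat sat. it purred loudly.", 12))
  one <- word_frequency_trend(single, "cat")
  expect_equal(nrow(one), 1L)
  expect_equal(one$mean_pct, 100 / 6, tolerance = 1e-12)
})

test_that("independent same-distribution derivations overlap strongly", {
  # Zipf weighting gives the vocabulary the stable rank structure real
  # corpora have; under flat weights all jargon words are exchangeable
  base <- list(n_journals = 10L, n_abstracts = 1500L,
               year_range = c(1990L, 2009L), zipf_s = 1)
  cfg_a <- do.call(generator_config, c(base, seed = 301L))
  cfg_b <- do.call(generator_config, c(base, seed = 302L))
  strata <- list(c(1990, 1999), c(2000, 2009))
  dcfg <- derivation_config(strata = strata, n_per_stratum = 600L, k = 100L)
  wl_a <- derive_science_common_words(generate_corpus(cfg_a)$records, dcfg)
  wl_b <- derive_science_common_words(generate_corpus(cfg_b)$records, dcfg)
  expect_gt(verification_overlap(wl_a, wl_b), 0.8)
})
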