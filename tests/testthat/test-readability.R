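test_that("syllable counting follows the three-step algorithm", {
  dict <- tiny_dict(c("present\t2,3", "science\t2", "rhythm\t2"))
  # step 1: no vowel and no y is not a word
  expect_equal(count_syllables("brr", dict), 0L)
  # step 2: dictionary lookup takes the longer alternative
  expect_equal(count_syllables("present", dict), 3L)
  expect_equal(count_syllables("science", dict), 2L)
  # step 3: vowel runs count once (diphthongs not double-counted)...
  expect_equal(count_syllables("bloorpy", dict), 2L)  # "oo" + terminal y
  expect_equal(count_syllables("bread", dict), 1L)    # "ea" one run
  # ...and a terminal y adds one syllable only in the fallback
  expect_equal(count_syllables("dry", dict), 1L)
  expect_equal(count_syllables("rhythm", dict), 2L)   # from dict, not step 3
})

test_that("language metrics match a hand count", {
  tok <- structure(
    list(doc_id = "hand",
         sentences = list(c("the", "cat", "sat"),
                          c("it", "purred", "loudly"))),
    class = "tokenized_abstract")
  common <- word_list(c("the", "cat", "sat", "it"))
  m <- language_metrics(tok, common = common, dict = tiny_dict("zz\t1"))
  expect_equal(m$n_words, 6L)
  expect_equal(m$n_sentences, 2L)
  # hand syllables: the 1, cat 1, sat 1, it 1, purred 2 (u, e), loudly 2 (ou + y)
  expect_equal(m$n_syllables, 8L)
  expect_equal(m$n_difficult, 2L)
  expect_equal(m$pct_difficult, 100 * 2 / 6, tolerance = 1e-12)
  expect_equal(m$words_per_sentence, 3)
  expect_equal(m$syllables_per_word, 8 / 6, tolerance = 1e-12)
})

test_that("pct_difficult spans its extremes", {
  tok <- segment("the cat sat. the cat ran.")
  all_common <- word_list(c("the", "cat", "sat", "ran"))
  none_common <- word_list("unrelated")
  d <- tiny_dict("zz\t1")
  expect_equal(language_metrics(tok, all_common, d)$pct_difficult, 0)
  expect_equal(language_metrics(tok, none_common, d)$pct_difficult, 100)
})

test_that("FRE and NDC match hand arithmetic from the printed equations", {
  m <- list(words_per_sentence = 10, syllables_per_word = 1.5,
            pct_difficult = 0)
  expect_equal(fre(m), 69.785, tolerance = 1e-9)
  expect_equal(ndc(m), 0.496, tolerance = 1e-9)
  m2 <- list(words_per_sentence = 3, syllables_per_word = 4 / 3)
  expect_equal(fre(m2), 206.835 - 3.045 - 112.8, tolerance = 1e-9)
  # boundary: exactly 5% difficult gets no adjustment
  expect_equal(ndc(list(pct_difficult = 5, words_per_sentence = 10)),
               1.2855, tolerance = 1e-9)
  expect_equal(ndc(list(pct_difficult = 20, words_per_sentence = 20)),
               7.7865, tolerance = 1e-9)
})

test_that("FRE falls linearly in syllables per word", {
  base <- list(words_per_sentence = 12, syllables_per_word = 1.4)
  up <- list(words_per_sentence = 12, syllables_per_word = 1.5)
  expect_equal(fre(base) - fre(up), 8.46, tolerance = 1e-9)
})

test_that("readability is monotone in its components", {
  wps <- seq(2, 40, length.out = 12)
  spw <- seq(1, 4, length.out = 12)
  pct <- seq(0, 100, length.out = 12)
  f_wps <- fre(list(words_per_sentence = wps, syllables_per_word = 1.5))
  f_spw <- fre(list(words_per_sentence = 10, syllables_per_word = spw))
  expect_true(all(diff(f_wps) < 0) && all(diff(f_spw) < 0))
  n_pct <- ndc(list(pct_difficult = pct, words_per_sentence = 10))
  n_wps <- ndc(list(pct_difficult = 20, words_per_sentence = wps))
  expect_true(all(diff(n_pct) > 0) && all(diff(n_wps) > 0))
})

test_that("score_abstract reproduces a full hand trace", {
  rec <- list(doc_id = "t1",
              text = "the cat sat quietly. it purred loudly today.")
  common <- word_list(c("the", "cat", "sat", "it", "today"))
  dict <- tiny_dict("zz\t1")
  s <- score_abstract(rec, common = common, dict = dict)
  # hand: 8 words, 2 sentences, 13 syllables (quietly 2: "uie" run + y;
  # today 3: o, a, terminal y), 3 difficult (quietly, purred, loudly)
  expect_true(s$scoreable)
  expect_equal(s$metrics$n_words, 8L)
  expect_equal(s$metrics$n_syllables, 13L)
  expect_equal(s$fre, fre_oracle(8, 2, 13), tolerance = 1e-9)
  expect_equal(s$ndc, ndc_oracle(100 * 3 / 8, 8, 2), tolerance = 1e-9)
})

test_that("all-common monosyllables in 5-word sentences hit the closed form", {
  rec <- list(doc_id = "t2", text = "the cat sat on mat. the dog ran to park.")
  common <- word_list(c("the", "cat", "sat", "on", "mat", "dog", "ran",
                        "to", "park"))
  s <- score_abstract(rec, common = common, dict = tiny_dict("zz\t1"))
  expect_equal(s$fre, 206.835 - 5.075 - 84.6, tolerance = 1e-9)
  expect_equal(s$ndc, 0.248, tolerance = 1e-9)
})

test_that("empty-after-cleaning abstracts are flagged unscoreable", {
  rec <- list(doc_id = "t3", text = "42 17 (3)")
  s <- suppressMessages(score_abstract(rec))
  expect_false(s$scoreable)
  expect_true(is.na(s$fre) && is.na(s$ndc))
})

test_that("vectorised corpus scoring equals per-document scoring", {
  gen <- generate_corpus(small_config(n_abstracts = 60L, seed = 11L))
  common <- ndc_common_words()
  dict <- syllable_dictionary()
  corpus <- score_corpus(gen$records, common, dict)
  for (i in c(1L, 7L, 23L, 60L)) {
    s <- score_abstract(gen$records[i, ], common, dict)
    expect_equal(corpus$fre[i], s$fre, tolerance = 1e-12)
    expect_equal(corpus$ndc[i], s$ndc, tolerance = 1e-12)
    expect_equal(corpus$n_words[i], s$metrics$n_words)
    expect_equal(corpus$n_syllables[i], s$metrics$n_syllables)
  }
})

test_that("FRE and NDC are negatively correlated on synthetic corpora", {
  gen <- generate_corpus(small_config(n_abstracts = 800L, seed = 5L))
  sc <- score_corpus(gen$records)
  r <- stats::cor(sc$fre, sc$ndc)
  expect_lt(r, -0.3)
})
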