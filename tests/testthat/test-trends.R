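scored_fixture <- function(n_per_year, years, fre_vals) {
  k <- sum(n_per_year)
  tibble::tibble(
    doc_id = sprintf("d%03d", seq_len(k)),
    journal = "J1",
    year = rep(years, n_per_year),
    n_authors = 3L,
    syllables_per_word = 1.5, words_per_sentence = 10,
    pct_difficult = 20, ndc = 5,
    fre = rep(fre_vals, n_per_year),
    scoreable = TRUE
  )
}

test_that("yearly summaries exclude sparse years and match hand means", {
  s <- scored_fixture(c(9L, 12L), c(1999L, 2000L), c(50, 40))
  ys <- yearly_summary(s, min_n = 10L)
  expect_equal(ys$year, 2000L)  # the 9-abstract year is excluded
  expect_equal(ys$mean_fre, 40)

  s2 <- tibble::tibble(
    doc_id = sprintf("d%02d", 1:24), journal = "J", n_authors = 2L,
    year = rep(c(2001L, 2002L), each = 12L),
    syllables_per_word = rep(c(1.2, 1.8), each = 12L),
    words_per_sentence = 10, pct_difficult = 10, ndc = rep(c(2, 4), each = 12L),
    fre = rep(c(60, 30), each = 12L), scoreable = TRUE
  )
  ys2 <- yearly_summary(s2)
  expect_equal(ys2$mean_fre, c(60, 30))
  expect_equal(ys2$mean_spw, c(1.2, 1.8))
  expect_equal(ys2$n_abstracts, c(12L, 12L))

  expect_error(yearly_summary(scored_fixture(5L, 2000L, 50), min_n = 10L),
               "at least 10")
})

test_that("ten identical scores average to themselves", {
  s <- scored_fixture(10L, 2005L, 43.21)
  expect_equal(yearly_summary(s)$mean_fre, 43.21)
})

test_that("pearson_trend matches the textbook formula and handles edge cases", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.3)
  tr <- pearson_trend(x, y)
  expect_equal(tr$r, pearson_oracle(x, y), tolerance = 1e-12)
  expect_equal(tr$n, 5L)
  expect_true(tr$ci_low <= tr$r && tr$r <= tr$ci_high)
  expect_true(tr$ci_low >= -1 && tr$ci_high <= 1)

  expect_equal(pearson_trend(1:10, 2 * (1:10) + 3)$r, 1.0, tolerance = 1e-12)
  expect_error(pearson_trend(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_trend(1:2, 2:3), "at least 3")
})

test_that("paired correlation aligns by doc_id and rejects mismatches", {
  a <- tibble::tibble(doc_id = c("x", "y", "z", "w"), score = c(1, 2, 3, 5))
  b <- a[c(3, 1, 4, 2), ]
  expect_equal(paired_correlation(a, b)$r, 1.0, tolerance = 1e-12)
  neg <- b
  neg$score <- -neg$score
  expect_equal(paired_correlation(a, neg)$r, -1.0, tolerance = 1e-12)

  four_b <- tibble::tibble(doc_id = a$doc_id, score = c(2.0, 1.5, 4.1, 4.0))
  expect_equal(paired_correlation(a, four_b)$r,
               pearson_oracle(a$score, four_b$score), tolerance = 1e-12)

  expect_error(
    paired_correlation(a, tibble::tibble(doc_id = c("x", "y", "q", "w"),
                                         score = 1:4)),
    "misaligned")
})

test_that("the model ladder orders nested fits and recovers a null slope", {
  cfg <- small_config(n_abstracts = 1000L, seed = 31L,
                      jargon_weight_slope = 0, sentence_length_slope = 0,
                      journal_slope_sd = 0, author_effect = 0)
  sc <- score_corpus(generate_corpus(cfg)$records)
  lad <- suppressWarnings(fit_mixed_models(sc, "fre"))
  tab <- lad$table
  # M1 nests M0: its maximised log-likelihood cannot be lower
  ll <- vapply(lad$models, function(m) as.numeric(stats::logLik(m)), numeric(1))
  expect_gte(ll["M1"], ll["M0"])
  expect_gte(ll["M2"], ll["M1"])
  # zero generated trend: the M1 year CI should cover 0 (nominal coverage)
  m1 <- tab[tab$model == "M1", ]
  expect_true(m1$ci_low < 0.15 && m1$ci_high > -0.15)
  expect_equal(sort(tab$model), c("M0", "M1", "M2"))
  expect_true(all(tab$daic >= 0) && all(tab$dbic >= 0))
})

test_that("year centering changes neither the slope nor the fit criteria", {
  gen <- generate_corpus(small_config(n_abstracts = 800L, seed = 41L))
  sc <- score_corpus(gen$records)
  a <- fit_mixed_models(sc, "fre", center_year = TRUE)
  b <- suppressWarnings(fit_mixed_models(sc, "fre", center_year = FALSE))
  # M1 is a fixed-effect reparameterisation: essentially exact; the
  # uncentered M2 optimum is found less precisely, which is the reason
  # centering is the default
  expect_equal(a$table$beta[a$table$model == "M1"],
               b$table$beta[b$table$model == "M1"], tolerance = 1e-6)
  expect_equal(a$table$beta[a$table$model == "M2"],
               b$table$beta[b$table$model == "M2"], tolerance = 0.02)
  expect_equal(a$table$aic[a$table$model == "M1"],
               b$table$aic[b$table$model == "M1"], tolerance = 1e-6)
  expect_lt(abs(a$table$aic[a$table$model == "M2"] -
                b$table$aic[b$table$model == "M2"]), 2)
})

test_that("a single-journal corpus degrades gracefully", {
  cfg <- small_config(n_journals = 1L, n_abstracts = 300L, seed = 51L,
                      journal_intercept_sd = 0, journal_slope_sd = 0)
  sc <- score_corpus(generate_corpus(cfg)$records)
  expect_warning(lad <- fit_mixed_models(sc, "fre"), "degenerate")
  expect_true(lad$degenerate)
  expect_equal(lad$table$model, "M1")
  expect_true(is.finite(lad$table$beta))
})

test_that("the author model filters its subset and degenerate inputs", {
  gen <- generate_corpus(small_config(n_abstracts = 500L, seed = 61L))
  sc <- score_corpus(gen$records)
  sc$n_authors[1:20] <- NA_integer_
  sc$n_authors[21] <- 11L
  full <- suppressMessages(author_effect_model(sc, "fre",
                                               subset_1_to_10 = FALSE))
  expect_message(
    sub <- author_effect_model(sc, "fre", subset_1_to_10 = TRUE),
    "20 record\\(s\\) lacking author information")
  expect_equal(full$n_obs, sum(sc$scoreable) - 20L)
  expect_equal(sub$n_obs, full$n_obs - sum(sc$n_authors > 10L, na.rm = TRUE))
  expect_setequal(sub$table$term, c("year", "authors"))

  sc$n_authors <- 4L
  expect_error(author_effect_model(sc, "fre"), "identical")
})

test_that("field slope summaries average member journals with SE", {
  slopes <- tibble::tibble(
    journal = c("Ja", "Jb", "Jc", "Jd"),
    intercept = 0,
    slope = c(-1, -2, -3, -0.5)
  )
  fmap <- tibble::tibble(
    journal = c("Ja", "Jb", "Jc", "Jc", "Jd"),
    field = c("neuro", "neuro", "neuro", "clinical", "solo")
  )
  out <- summarize_field_slopes(slopes, fmap)
  neuro <- out[out$field == "neuro", ]
  expect_equal(neuro$mean_slope, -2)
  expect_equal(neuro$se_slope, 1 / sqrt(3), tolerance = 1e-9)
  # a journal in two fields appears in both summaries
  expect_equal(out$mean_slope[out$field == "clinical"], -3)
  # single-journal field: SE undefined
  expect_true(is.na(out$se_slope[out$field == "solo"]))

  expect_error(summarize_field_slopes(slopes, fmap[1:3, ]), "Jd")
})

test_that("journal slopes combine the fixed effect with the BLUPs", {
  gen <- generate_corpus(small_config(n_abstracts = 900L, seed = 71L))
  sc <- score_corpus(gen$records)
  lad <- fit_mixed_models(sc, "fre")
  js <- journal_slopes(lad)
  expect_equal(nrow(js), 8L)
  beta <- lad$table$beta[lad$table$model == "M2"]
  expect_equal(mean(js$slope), beta, tolerance = 0.05)
  # slopes must vary across journals when the generator gave them spread
  expect_gt(stats::sd(js$slope), 0)
})
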