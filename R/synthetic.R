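#' Configuration for the synthetic abstract-corpus generator
#'
#' The generator emulates the structure the trend analyses assume: each
#' document's latent jargon weight (the probability a word is drawn from the
#' multi-syllable jargon vocabulary rather than the easy vocabulary) drifts
#' linearly with publication year, varies across journals through random
#' intercepts and slopes, and shifts with the number of authors; mean
#' sentence length drifts linearly with year as well. Because words are
#' sampled from flat vocabularies by default, the implied population slopes
#' of every readability component are available in closed form
#' ([expected_slopes()]).
#'
#' When `jargon_weight_slope` or `author_effect` is `NULL` (the default) it
#' is calibrated from the vocabularies so the implied population FRE trend
#' is -0.19 FRE units per year and the implied per-author FRE effect is
#' -0.24 — the magnitudes reported for the real abstract corpus — making
#' recovery tests representative of the actual analysis.
#'
#' @param n_journals Number of journals (default 20).
#' @param n_abstracts Number of abstracts (default 5000).
#' @param year_range `c(start, end)` publication years (default 1976-2015).
#' @param easy_vocab [word_list()] of low-syllable words; default: the
#'   monosyllabic words of the bundled common-word list.
#' @param jargon_vocab [word_list()] of multi-syllable words outside the
#'   common list; default: the 3+ syllable words of the bundled jargon list.
#' @param jargon_weight_base Jargon weight at the start year (default 0.25).
#' @param jargon_weight_slope Per-year change in jargon weight; `NULL` to
#'   calibrate (see above).
#' @param sentence_length_base Mean words per sentence at the start year
#'   (default 12).
#' @param sentence_length_slope Per-year change in mean sentence length
#'   (default 0.02).
#' @param journal_intercept_sd SD of journal random intercepts, jargon-weight
#'   units (default 0.03).
#' @param journal_slope_sd SD of journal random slopes, jargon-weight units
#'   per year (default 4e-4).
#' @param author_lambda Mean author count; counts are `1 + Poisson(lambda -
#'   1)` so every article has at least one author (default 4).
#' @param author_effect Per-author shift in jargon weight; `NULL` to
#'   calibrate.
#' @param n_sentences_mean Mean sentences per abstract; counts are `4 +
#'   Poisson(mean - 4)` (default 7).
#' @param zipf_s Zipf exponent for within-vocabulary word weights; 0 (the
#'   default) samples words uniformly, which keeps the closed-form
#'   expectations exact. Positive values give the rank-frequency structure
#'   real text has and are used for word-ranking properties, not for slope
#'   recovery.
#' @param seed Random seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_journals = 20L, n_abstracts = 5000L,
                             year_range = c(1976L, 2015L),
                             easy_vocab = NULL, jargon_vocab = NULL,
                             jargon_weight_base = 0.25,
                             jargon_weight_slope = NULL,
                             sentence_length_base = 12,
                             sentence_length_slope = 0.02,
                             journal_intercept_sd = 0.03,
                             journal_slope_sd = 4e-4,
                             author_lambda = 4,
                             author_effect = NULL,
                             n_sentences_mean = 7,
                             zipf_s = 0,
                             seed = 1L) {
  dict <- syllable_dictionary()
  common <- ndc_common_words()
  if (is.null(easy_vocab)) easy_vocab <- default_easy_vocab(common, dict)
  if (is.null(jargon_vocab)) jargon_vocab <- default_jargon_vocab(common, dict)
  stopifnot(inherits(easy_vocab, "word_list"),
            inherits(jargon_vocab, "word_list"),
            length(easy_vocab$words) > 0L, length(jargon_vocab$words) > 0L,
            n_journals >= 1L, n_abstracts >= 1L,
            year_range[1L] <= year_range[2L],
            sentence_length_base >= 2, n_sentences_mean >= 4,
            jargon_weight_base >= 0, jargon_weight_base <= 1,
            author_lambda >= 1, zipf_s >= 0)
  if (length(intersect(easy_vocab$words, jargon_vocab$words)) > 0L) {
    stop("easy and jargon vocabularies must be disjoint")
  }
  bad <- c(easy_vocab$words, jargon_vocab$words)
  bad <- bad[nchar(bad) < 2L | grepl("^[acgtu]{6,}$", bad)]
  if (length(bad) > 0L) {
    stop("vocabulary words would be removed by cleaning rules: ",
         paste(bad, collapse = ", "))
  }
  cfg <- list(
    n_journals = as.integer(n_journals),
    n_abstracts = as.integer(n_abstracts),
    year_range = as.integer(year_range),
    easy_vocab = easy_vocab, jargon_vocab = jargon_vocab,
    jargon_weight_base = jargon_weight_base,
    jargon_weight_slope = jargon_weight_slope,
    sentence_length_base = sentence_length_base,
    sentence_length_slope = sentence_length_slope,
    journal_intercept_sd = journal_intercept_sd,
    journal_slope_sd = journal_slope_sd,
    author_lambda = author_lambda,
    author_effect = author_effect,
    n_sentences_mean = n_sentences_mean,
    zipf_s = zipf_s,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  ds <- syllable_gap(cfg, dict)
  if (is.null(cfg$jargon_weight_slope)) {
    cfg$jargon_weight_slope <-
      (0.19 - 1.015 * cfg$sentence_length_slope) / (84.6 * ds)
  }
  if (is.null(cfg$author_effect)) {
    cfg$author_effect <- 0.24 / (84.6 * ds)
  }
  span <- diff(cfg$year_range)
  p_end <- cfg$jargon_weight_base + cfg$jargon_weight_slope * span
  if (p_end < 0 || p_end > 1) {
    stop("jargon weight leaves [0, 1] over the year range")
  }
  cfg
}

default_easy_vocab <- function(common = ndc_common_words(),
                               dict = syllable_dictionary()) {
  w <- common$words
  w <- w[nchar(w) >= 2L & nchar(w) <= 6L & !grepl("'", w) &
           !grepl("^[acgtu]{6,}$", w)]
  w <- w[syllable_counts(w, dict) == 1L]
  word_list(utils::head(w, 200L), name = "easy_vocab",
            provenance = "monosyllabic subset of the bundled common-word list")
}

default_jargon_vocab <- function(common = ndc_common_words(),
                                 dict = syllable_dictionary()) {
  w <- science_jargon_words()$words
  w <- setdiff(w, common$words)
  w <- w[syllable_counts(w, dict) >= 3L]
  word_list(utils::head(w, 200L), name = "jargon_vocab",
            provenance = "3+ syllable subset of the bundled jargon list")
}

zipf_weights <- function(n, s) {
  if (s == 0) rep(1 / n, n) else {
    w <- 1 / seq_len(n)^s
    w / sum(w)
  }
}

# difference in mean syllables per word between jargon and easy vocabularies
syllable_gap <- function(cfg, dict = syllable_dictionary()) {
  we <- zipf_weights(length(cfg$easy_vocab$words), cfg$zipf_s)
  wj <- zipf_weights(length(cfg$jargon_vocab$words), cfg$zipf_s)
  sum(wj * syllable_counts(cfg$jargon_vocab$words, dict)) -
    sum(we * syllable_counts(cfg$easy_vocab$words, dict))
}

#' Closed-form expected slopes implied by a generator configuration
#'
#' With flat (or fixed Zipf) vocabulary weights, every readability component
#' is a linear mixture of the two vocabularies' known properties, so the
#' population year-slopes are available exactly: the slope of the percentage
#' of difficult words is `100 * jargon_weight_slope` times the
#' difficult-fraction gap between vocabularies; the syllables-per-word slope
#' is the syllable-mean gap times the jargon-weight slope; FRE and NDC
#' slopes follow by plugging these into the formulas. These are the recovery
#' targets for the model-fitting tests.
#'
#' @param cfg A [generator_config()].
#' @param common Common-word list used at scoring time.
#' @param dict Syllable dictionary used at scoring time.
#' @return A list of class `ground_truth_slopes`: per-year slopes
#'   `pct_difficult`, `syllables_per_word`, `words_per_sentence`, `fre`,
#'   `ndc`; per-author effects `fre_per_author`, `ndc_per_author`; and the
#'   journal random-slope SD on the FRE scale, `journal_fre_slope_sd`.
#' @export
expected_slopes <- function(cfg, common = ndc_common_words(),
                            dict = syllable_dictionary()) {
  stopifnot(inherits(cfg, "generator_config"))
  we <- zipf_weights(length(cfg$easy_vocab$words), cfg$zipf_s)
  wj <- zipf_weights(length(cfg$jargon_vocab$words), cfg$zipf_s)
  s_e <- sum(we * syllable_counts(cfg$easy_vocab$words, dict))
  s_j <- sum(wj * syllable_counts(cfg$jargon_vocab$words, dict))
  d_e <- sum(we * !(cfg$easy_vocab$words %in% common$words))
  d_j <- sum(wj * !(cfg$jargon_vocab$words %in% common$words))
  b <- cfg$jargon_weight_slope
  a <- cfg$author_effect
  wps_slope <- cfg$sentence_length_slope
  spw_slope <- (s_j - s_e) * b
  pdiff_slope <- 100 * (d_j - d_e) * b
  structure(
    list(
      pct_difficult = pdiff_slope,
      syllables_per_word = spw_slope,
      words_per_sentence = wps_slope,
      fre = -1.015 * wps_slope - 84.6 * spw_slope,
      ndc = 0.1579 * pdiff_slope + 0.0496 * wps_slope,
      fre_per_author = -84.6 * (s_j - s_e) * a,
      ndc_per_author = 0.1579 * 100 * (d_j - d_e) * a,
      journal_fre_slope_sd = 84.6 * (s_j - s_e) * cfg$journal_slope_sd
    ),
    class = "ground_truth_slopes"
  )
}

#' Generate a synthetic abstract corpus with known ground truth
#'
#' Draws, per document: a journal (uniform), a year (uniform over the
#' range), an author count (`1 + Poisson`), and a latent jargon weight
#' `clamp(base + slope * (year - start) + journal intercept + journal slope
#' * (year - start) + author_effect * (n_authors - lambda), 0, 1)`. Sentence
#' counts and lengths come from shifted Poisson distributions (minimum two
#' words, so no sentence is dropped by segmentation); each word is drawn
#' from the jargon vocabulary with the latent weight, otherwise from the
#' easy vocabulary, and the text is rendered as period-terminated
#' sentences. Deterministic under `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return A list with `records` (abstract-record tibble: `doc_id`,
#'   `journal`, `year`, `n_authors`, `text`) and `truth` (journal effects,
#'   per-document latent weights, clamped fraction, and the
#'   [expected_slopes()] summary).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_abstracts
    journals <- sprintf("journal_%02d", seq_len(cfg$n_journals))
    j_int <- stats::rnorm(cfg$n_journals, 0, cfg$journal_intercept_sd)
    j_slp <- stats::rnorm(cfg$n_journals, 0, cfg$journal_slope_sd)
    ji <- sample.int(cfg$n_journals, n, replace = TRUE)
    year <- sample(seq(cfg$year_range[1L], cfg$year_range[2L]), n,
                   replace = TRUE)
    t <- year - cfg$year_range[1L]
    n_authors <- 1L + stats::rpois(n, cfg$author_lambda - 1)
    p_raw <- cfg$jargon_weight_base + cfg$jargon_weight_slope * t +
      j_int[ji] + j_slp[ji] * t +
      cfg$author_effect * (n_authors - cfg$author_lambda)
    p <- pmin(1, pmax(0, p_raw))
    clamped <- mean(p != p_raw)
    if (clamped > 0.10) {
      warning(sprintf(
        "jargon weight clamped for %.1f%% of documents; config piles up at the boundary",
        100 * clamped))
    }

    n_sent <- 4L + stats::rpois(n, cfg$n_sentences_mean - 4)
    doc_of_sent <- rep.int(seq_len(n), n_sent)
    mu <- cfg$sentence_length_base + cfg$sentence_length_slope * t
    sent_len <- 2L + stats::rpois(length(doc_of_sent),
                                  pmax(0, mu[doc_of_sent] - 2))
    doc_of_word <- rep.int(doc_of_sent, sent_len)
    n_words <- length(doc_of_word)

    we <- zipf_weights(length(cfg$easy_vocab$words), cfg$zipf_s)
    wj <- zipf_weights(length(cfg$jargon_vocab$words), cfg$zipf_s)
    is_jargon <- stats::runif(n_words) < p[doc_of_word]
    words <- character(n_words)
    words[is_jargon] <- sample(cfg$jargon_vocab$words, sum(is_jargon),
                               replace = TRUE, prob = wj)
    words[!is_jargon] <- sample(cfg$easy_vocab$words, sum(!is_jargon),
                                replace = TRUE, prob = we)

    sent_id <- rep.int(seq_along(sent_len), sent_len)
    sent_text <- vapply(split(words, sent_id), paste, character(1),
                        collapse = " ")
    text <- vapply(split(unname(sent_text), doc_of_sent), paste, character(1),
                   collapse = ". ")
    text <- paste0(text, ".")

    records <- tibble::tibble(
      doc_id = sprintf("doc_%06d", seq_len(n)),
      journal = journals[ji],
      year = as.integer(year),
      n_authors = as.integer(n_authors),
      text = text
    )
    truth <- list(
      journal_intercepts = stats::setNames(j_int, journals),
      journal_slopes = stats::setNames(j_slp, journals),
      latent_jargon_weight = p,
      clamped_fraction = clamped,
      expected = expected_slopes(cfg)
    )
    list(records = records, truth = truth)
  })
}

#' Write a generator ground-truth report
#'
#' @param truth The `truth` element of [generate_corpus()] output.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$latent_jargon_weight <- NULL  # per-document detail, too bulky to report
  out$expected <- unclass(out$expected)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
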