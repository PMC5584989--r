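#' Count the syllables of a word
#'
#' Three-step counter. Step 1: a token without any of a, e, i, o, u or 'y'
#' is not a word and counts 0 syllables. Step 2: if the word is in the
#' syllable dictionary, use its count; when the dictionary offers several
#' alternatives the longer one is chosen. Step 3: otherwise count vowel
#' groups — each maximal run of consecutive a/e/i/o/u counts once, so
#' diphthongs are not double-counted — and add one syllable for a terminal
#' 'y'.
#'
#' @param word A single lowercase token.
#' @param dict A [syllable_dictionary()].
#' @return Nonnegative integer syllable count.
#' @examples
#' count_syllables("readability")
#' count_syllables("brr")   # not a word: 0
#' @export
count_syllables <- function(word, dict = syllable_dictionary()) {
  stopifnot(is.character(word), length(word) == 1L, nzchar(word))
  syllable_counts(word, dict)
}

# vectorised three-step syllable counter
syllable_counts <- function(words, dict) {
  out <- integer(length(words))
  has_vowel <- grepl("[aeiouy]", words)
  idx <- match(words, dict$word)
  from_dict <- has_vowel & !is.na(idx)
  out[from_dict] <- dict$max_count[idx[from_dict]]
  fb <- has_vowel & is.na(idx)
  if (any(fb)) {
    w <- words[fb]
    runs <- vapply(gregexpr("[aeiou]+", w), function(m) {
      if (m[1L] == -1L) 0L else length(m)
    }, integer(1))
    out[fb] <- runs + as.integer(grepl("y$", w))
  }
  out
}

#' Language metrics of a tokenized abstract
#'
#' Computes the component counts behind both readability formulas: words are
#' tokens with at least one syllable; sentences are the retained sentences
#' (one per terminal period); difficult words are tokens absent from the
#' common-word list, counted per occurrence.
#'
#' @param tok A [segment()]ed abstract.
#' @param common The common-word [word_list()]; defaults to the bundled list.
#' @param dict A [syllable_dictionary()].
#' @return A list of class `language_metrics` with `n_words`, `n_sentences`,
#'   `n_syllables`, `n_difficult`, `words_per_sentence`,
#'   `syllables_per_word`, `pct_difficult`, or an unscoreable stub
#'   (`n_sentences = 0`) when no sentence survived.
#' @export
language_metrics <- function(tok, common = ndc_common_words(),
                             dict = syllable_dictionary()) {
  stopifnot(inherits(tok, "tokenized_abstract"), inherits(common, "word_list"))
  tokens <- unlist(tok$sentences, use.names = FALSE)
  if (length(tok$sentences) == 0L) {
    return(structure(
      list(n_words = 0L, n_sentences = 0L, n_syllables = 0L, n_difficult = 0L,
           words_per_sentence = NA_real_, syllables_per_word = NA_real_,
           pct_difficult = NA_real_),
      class = "language_metrics"
    ))
  }
  syl <- syllable_counts(tokens, dict)
  keep <- syl >= 1L
  n_words <- sum(keep)
  n_sentences <- length(tok$sentences)
  n_syllables <- sum(syl[keep])
  n_difficult <- sum(!(tokens[keep] %in% common$words))
  structure(
    list(
      n_words = n_words,
      n_sentences = n_sentences,
      n_syllables = n_syllables,
      n_difficult = n_difficult,
      words_per_sentence = n_words / n_sentences,
      syllables_per_word = n_syllables / n_words,
      pct_difficult = 100 * n_difficult / n_words
    ),
    class = "language_metrics"
  )
}

#' Flesch Reading Ease
#'
#' `FRE = 206.835 - 1.015 (words/sentences) - 84.6 (syllables/words)`.
#' Higher scores are easier to read; 0-30 is considered college-graduate
#' level.
#'
#' @param metrics A [language_metrics()] object (or any list with
#'   `words_per_sentence` and `syllables_per_word`).
#' @return Numeric FRE score.
#' @export
fre <- function(metrics) {
  206.835 - 1.015 * metrics$words_per_sentence -
    84.6 * metrics$syllables_per_word
}

#' New Dale-Chall readability score
#'
#' `NDC = 0.1579 * pct_difficult + 0.0496 (words/sentences)`, plus the
#' constant 3.6365 when the percentage of difficult words exceeds 5. The
#' score is computed on the entire text, not a 100-word sample. Higher
#' scores are harder to read.
#'
#' @param metrics A [language_metrics()] object (or any list with
#'   `pct_difficult` and `words_per_sentence`).
#' @return Numeric NDC score.
#' @export
ndc <- function(metrics) {
  raw <- 0.1579 * metrics$pct_difficult + 0.0496 * metrics$words_per_sentence
  raw + ifelse(!is.na(metrics$pct_difficult) & metrics$pct_difficult > 5,
               3.6365, 0)
}

#' Score a single abstract
#'
#' Composes [clean_text()], [segment()], [language_metrics()], [fre()] and
#' [ndc()] for one abstract record.
#'
#' @param rec A one-row data frame (or list) with `doc_id` and `text`.
#' @param common Common-word [word_list()].
#' @param dict [syllable_dictionary()].
#' @param preprocess Apply the cleaning rules first? `FALSE` reproduces the
#'   raw-text sensitivity mode.
#' @param rules [preprocess_rules()] used when `preprocess` is `TRUE`.
#' @return A list of class `readability_scores`: `doc_id`, `fre`, `ndc`,
#'   `metrics`, `scoreable`.
#' @export
score_abstract <- function(rec, common = ndc_common_words(),
                           dict = syllable_dictionary(), preprocess = TRUE,
                           rules = preprocess_rules()) {
  text <- if (preprocess) clean_text(rec$text, rules = rules) else rec$text
  tok <- segment(text, doc_id = rec$doc_id)
  m <- language_metrics(tok, common = common, dict = dict)
  scoreable <- m$n_sentences >= 1L && m$n_words >= 1L
  structure(
    list(
      doc_id = rec$doc_id,
      fre = if (scoreable) fre(m) else NA_real_,
      ndc = if (scoreable) ndc(m) else NA_real_,
      metrics = m,
      scoreable = scoreable
    ),
    class = "readability_scores"
  )
}

#' Score a corpus of abstracts
#'
#' Vectorised scoring of a whole corpus; produces exactly the same numbers
#' as [score_abstract()] applied row by row, but in a single pass. Documents
#' whose text is unusable after cleaning are flagged `scoreable = FALSE`
#' with a logged count and carry `NA` scores; downstream aggregation drops
#' them.
#'
#' @param records Tibble of abstract records with columns `doc_id`, `text`
#'   and (optionally) `journal`, `year`, `n_authors`, which are carried
#'   through.
#' @param common Common-word [word_list()].
#' @param dict [syllable_dictionary()].
#' @param preprocess Apply the cleaning rules first?
#' @param rules [preprocess_rules()].
#' @return A tibble with metadata columns plus `n_words`, `n_sentences`,
#'   `n_syllables`, `n_difficult`, `words_per_sentence`,
#'   `syllables_per_word`, `pct_difficult`, `fre`, `ndc`, `scoreable`.
#' @export
score_corpus <- function(records, common = ndc_common_words(),
                         dict = syllable_dictionary(), preprocess = TRUE,
                         rules = preprocess_rules()) {
  stopifnot(is.data.frame(records),
            all(c("doc_id", "text") %in% names(records)))
  n <- nrow(records)
  text <- if (preprocess) clean_text(records$text, rules = rules) else records$text

  sent_split <- strsplit(tolower(text), ".", fixed = TRUE)
  n_sent_raw <- lengths(sent_split)
  all_sent <- unlist(sent_split, use.names = FALSE)
  doc_of_sent <- rep.int(seq_len(n), n_sent_raw)

  tok_split <- strsplit(trimws(all_sent), "\\s+")
  all_tok <- unlist(tok_split, use.names = FALSE)
  sent_of_tok <- rep.int(seq_along(all_sent), lengths(tok_split))

  ok_tok <- nzchar(all_tok) & grepl("[aeiouy]", all_tok)
  all_tok <- all_tok[ok_tok]
  sent_of_tok <- sent_of_tok[ok_tok]

  # sentence retention: >= 2 tokens that can carry a syllable
  sent_size <- tabulate(sent_of_tok, nbins = length(all_sent))
  sent_keep <- sent_size >= 2L
  tok_keep <- sent_keep[sent_of_tok]
  all_tok <- all_tok[tok_keep]
  doc_of_tok <- doc_of_sent[sent_of_tok[tok_keep]]

  uniq <- unique(all_tok)
  syl_u <- syllable_counts(uniq, dict)
  diff_u <- !(uniq %in% common$words)
  iu <- match(all_tok, uniq)
  syl <- syl_u[iu]

  word <- syl >= 1L
  n_words <- tabulate(doc_of_tok[word], nbins = n)
  n_sentences <- tabulate(doc_of_sent[sent_keep], nbins = n)
  n_syllables <- as.integer(rowsum_int(syl[word], doc_of_tok[word], n))
  n_difficult <- tabulate(doc_of_tok[word][diff_u[iu][word]], nbins = n)

  scoreable <- n_sentences >= 1L & n_words >= 1L
  wps <- ifelse(scoreable, n_words / n_sentences, NA_real_)
  spw <- ifelse(scoreable, n_syllables / n_words, NA_real_)
  pdiff <- ifelse(scoreable, 100 * n_difficult / n_words, NA_real_)

  out <- tibble::as_tibble(records[intersect(
    c("doc_id", "journal", "year", "n_authors"), names(records))])
  out$n_words <- n_words
  out$n_sentences <- n_sentences
  out$n_syllables <- n_syllables
  out$n_difficult <- n_difficult
  out$words_per_sentence <- wps
  out$syllables_per_word <- spw
  out$pct_difficult <- pdiff
  out$fre <- fre(list(words_per_sentence = wps, syllables_per_word = spw))
  out$ndc <- ndc(list(pct_difficult = pdiff, words_per_sentence = wps))
  out$scoreable <- scoreable
  if (any(!scoreable)) {
    message(sum(!scoreable), " document(s) unscoreable and flagged")
  }
  out
}

# grouped integer sum with fixed group count (base rowsum drops empty groups)
rowsum_int <- function(x, g, n) {
  out <- numeric(n)
  if (length(x) > 0L) {
    s <- rowsum(x, g)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}
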