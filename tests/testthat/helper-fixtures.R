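# shared fixtures and independent oracles, built in code

# straight-line evaluations of the printed readability equations,
# deliberately independent of fre()/ndc()
fre_oracle <- function(words, sentences, syllables) {
  206.835 - 1.015 * (words / sentences) - 84.6 * (syllables / words)
}
ndc_oracle <- function(pct_difficult, words, sentences) {
  base <- 0.1579 * pct_difficult + 0.0496 * (words / sentences)
  if (pct_difficult > 5) base + 3.6365 else base
}

# textbook Pearson r from the definitional formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  (sum(x * y) - n * mean(x) * mean(y)) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
}

# brute-force word-frequency ranking over a full (unsampled) token stream
rank_words_oracle <- function(tokens, exclusion = character(0), k) {
  tokens <- tokens[!(tokens %in% exclusion)]
  tab <- sort(table(tokens), decreasing = TRUE)
  # ties broken alphabetically within equal frequency
  ord <- order(-as.integer(tab), names(tab))
  utils::head(names(tab)[ord], k)
}

# a tiny syllable dictionary written to disk
tiny_dict <- function(entries = c("present\t2,3", "science\t2", "rhythm\t2")) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(entries, path)
  syllable_dictionary(path)
}

# minimal well-formed abstract records
make_records <- function(texts, years = NULL, journals = NULL,
                         n_authors = NULL) {
  n <- length(texts)
  tibble::tibble(
    doc_id = sprintf("d%03d", seq_len(n)),
    journal = if (is.null(journals)) rep("J1", n) else journals,
    year = if (is.null(years)) rep(2000L, n) else as.integer(years),
    n_authors = if (is.null(n_authors)) rep(3L, n) else as.integer(n_authors),
    text = texts
  )
}

# before/after fixture per heuristic cleaning rule
cleaning_fixtures <- function() {
  list(
    abbreviations = c("we used e.g. the standard assay",
                      "we used the standard assay."),
    abbreviations_allcaps = c("total DNA. was then extracted quickly",
                              "total was then extracted quickly."),
    space_after_period = c("first sentence ends.second sentence starts here",
                           "first sentence ends. second sentence starts here."),
    final_period = c("no terminal period here",
                     "no terminal period here."),
    trailing_numbers = c("Values rose to 42. they fell later.",
                         "Values rose to. they fell later."),
    etc_period_kept = c("we used buffers etc. results follow here.",
                        "we used buffers etc. results follow here."),
    single_letters = c("a B c test remains a test",
                       "a test remains a test."),
    single_letter_keeps_I = c("here I stand alone today",
                              "here I stand alone today."),
    nucleotide = c("the motif ACGTACGT was found twice",
                   "the motif was found twice."),
    hyphens = c("state-of-the-art", "state of the art."),
    binomial = c("cultures of E. coli grew overnight",
                 "cultures of coli grew overnight."),
    boilerplate = c("main findings reported here. Copyright 2011 Elsevier Inc. All rights reserved.",
                    "main findings reported here."),
    digits_and_punct = c("we found 17 cells (p < 0.05); growth, overall, doubled",
                         "we found cells growth overall doubled.")
  )
}

# small generator config for fast tests
small_config <- function(n_journals = 8L, n_abstracts = 600L,
                         year_range = c(1990L, 2009L), ...) {
  generator_config(n_journals = n_journals, n_abstracts = n_abstracts,
                   year_range = year_range, ...)
}
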