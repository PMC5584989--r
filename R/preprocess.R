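#' Preprocessing rule configuration
#'
#' Each heuristic cleaning rule applied by [clean_text()] can be toggled, and
#' the boilerplate phrase list replaced, mirroring the quality-control origin
#' of the rules: they are documented, editable heuristics, not recovered
#' ground truth. Passing a key-value config file (lines of `rule = TRUE/FALSE`
#' or `boilerplate_file = <path>`) overrides the defaults.
#'
#' @param file Optional path to a key-value config file.
#' @param ... Named overrides of individual rules (see Details).
#' @details Rules, in application order: `abbreviations`,
#'   `space_after_period`, `final_period`, `trailing_numbers`,
#'   `single_letters`, `nucleotide_sequences`, `hyphens`, `binomial_periods`,
#'   `boilerplate`. (Keeping the period of a sentence ending in "etc." needs
#'   no rule of its own: the abbreviation pattern deliberately does not match
#'   it.) A final always-on pass removes remaining digit-only tokens, stray
#'   digits and punctuation other than sentence-ending periods.
#' @return A list of class `preprocess_rules`.
#' @export
preprocess_rules <- function(file = NULL, ...) {
  rules <- list(
    abbreviations = TRUE,
    space_after_period = TRUE,
    final_period = TRUE,
    trailing_numbers = TRUE,
    single_letters = TRUE,
    nucleotide_sequences = TRUE,
    hyphens = TRUE,
    binomial_periods = TRUE,
    boilerplate = TRUE,
    boilerplate_phrases = boilerplate_phrases()
  )
  if (!is.null(file)) {
    lines <- readLines(file, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
      key <- trimws(kv[1L]); val <- trimws(kv[2L])
      if (key == "boilerplate_file") {
        rules$boilerplate_phrases <- readLines(val, warn = FALSE)
      } else if (key %in% names(rules)) {
        rules[[key]] <- as.logical(val)
      } else {
        stop("unknown preprocessing rule: '", key, "'")
      }
    }
  }
  dots <- list(...)
  for (key in names(dots)) {
    if (!key %in% names(rules)) stop("unknown preprocessing rule: '", key, "'")
    rules[[key]] <- dots[[key]]
  }
  structure(rules, class = "preprocess_rules")
}

#' Clean raw abstract text with rule-based heuristics
#'
#' Applies, in order: (1) removal of abbreviations (letter-period groups such
#' as "e.g." or "U.S.A.", and mid-sentence all-caps tokens of 2-5 letters
#' ending in a period); (2) insertion of a space after a period directly
#' followed by a letter; (3) a terminal period when the text does not end
#' with one; (4) removal of numbers that end sentences, keeping the period;
#' (5) sentences ending in "etc." keep their period; (6) removal of
#' single-letter words except "a", "A" and "I"; (7) removal of nucleic-acid
#' sequence tokens (length >= 6, letters A/C/G/T/U only); (8) hyphens
#' replaced by a space; (9) removal of periods from binomial nomenclature
#' ("E. coli" becomes "E coli"; the lone capital then falls to rule 6);
#' (10) stripping of trailing copyright/funding boilerplate. A final pass
#' removes remaining digit-only tokens, digits and punctuation other than
#' sentence-ending periods, and re-applies the single-letter rule to
#' binomial leftovers. The result contains only words and sentence-ending
#' periods. `clean_text` is idempotent.
#'
#' @param x Character vector of raw abstract texts (vectorised).
#' @param rules A [preprocess_rules()] configuration.
#' @return Character vector of cleaned texts; a text with no surviving words
#'   becomes the empty string.
#' @examples
#' clean_text("state-of-the-art methods (see e.g. Smith 2001) were used")
#' @export
clean_text <- function(x, rules = preprocess_rules()) {
  stopifnot(is.character(x))
  y <- trimws(x)

  if (isTRUE(rules$abbreviations)) {
    # letter-period groups; "etc." has a single trailing period and is untouched
    y <- gsub("\\b(?:[A-Za-z]\\.){2,}", "", y, perl = TRUE)
    # all-caps token ending in a period with the sentence continuing in lowercase;
    # single capitals are left for the binomial rule
    y <- gsub("\\b[A-Z]{2,5}\\.(?=\\s*[a-z])", "", y, perl = TRUE)
  }
  if (isTRUE(rules$space_after_period)) {
    y <- gsub("\\.(?=[A-Za-z])", ". ", y, perl = TRUE)
  }
  if (isTRUE(rules$final_period)) {
    miss <- nzchar(y) & !grepl("\\.\\s*$", y)
    y[miss] <- paste0(sub("\\s+$", "", y[miss]), ".")
  }
  if (isTRUE(rules$trailing_numbers)) {
    y <- gsub("(?<=\\s|^)[0-9]+(?:[.,][0-9]+)*%?\\s*\\.(?=\\s|$)", ".", y, perl = TRUE)
  }
  if (isTRUE(rules$single_letters)) {
    # single capitals opening a binomial ("E. coli") are left for rule 9
    y <- drop_single_letters(y, protect_binomial = TRUE)
  }
  if (isTRUE(rules$nucleotide_sequences)) {
    y <- gsub("(?<![A-Za-z])[ACGTUacgtu]{6,}(?![A-Za-z])", "", y, perl = TRUE)
  }
  if (isTRUE(rules$hyphens)) {
    y <- gsub("[-‐–—]+", " ", y)
  }
  if (isTRUE(rules$binomial_periods)) {
    y <- gsub("\\b([A-Z])\\.\\s*(?=[a-z])", "\\1 ", y, perl = TRUE)
  }
  if (isTRUE(rules$boilerplate) && length(rules$boilerplate_phrases) > 0L) {
    pat <- paste(vapply(rules$boilerplate_phrases, escape_regex, character(1)),
                 collapse = "|")
    m <- regexpr(pat, y, ignore.case = TRUE)
    hit <- m > 0L
    y[hit] <- substr(y[hit], 1L, m[hit] - 1L)
  }

  # final pass: bare numbers, stray digits, punctuation, binomial leftovers
  y <- gsub("(?<![A-Za-z0-9])[0-9]+(?:[.,][0-9]+)*(?![A-Za-z0-9])", "", y, perl = TRUE)
  y <- gsub("[0-9]+", "", y)
  y <- gsub("[^A-Za-z'. ]+", " ", gsub("\\s+", " ", y))
  y <- gsub("(?<![A-Za-z])'|'(?![A-Za-z])", " ", y, perl = TRUE)
  if (isTRUE(rules$single_letters)) y <- drop_single_letters(y)
  y <- gsub("\\s*\\.\\s*", ". ", y)   # one space after every period
  y <- gsub("(\\. )+", ". ", y)       # collapse empty sentences
  y <- trimws(gsub("\\s+", " ", y))
  nonempty <- grepl("[A-Za-z]", y)
  y[!nonempty] <- ""
  miss <- nonempty & !grepl("\\.$", y)
  y[miss] <- paste0(y[miss], ".")
  n_empty <- sum(!nonempty & nzchar(x))
  if (n_empty > 0L) {
    message(n_empty, " text(s) had no words left after cleaning")
  }
  y
}

# remove single-letter words except a, A, I (keep any trailing period);
# with protect_binomial, a lone capital starting "X. lowercase" survives
drop_single_letters <- function(y, protect_binomial = FALSE) {
  upper <- if (protect_binomial) "[B-HJ-Z](?!\\.\\s*[a-z])" else "[B-HJ-Z]"
  pat <- paste0("(?<![A-Za-z'])(?:", upper, "|[b-z])(?![A-Za-z'])")
  y <- gsub(pat, "", y, perl = TRUE)
  gsub("\\s+\\.", ".", gsub("\\s+", " ", y))
}

escape_regex <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)

#' Segment cleaned text into sentences of word tokens
#'
#' Splits cleaned text on periods, tokenizes each sentence on whitespace and
#' lowercases the tokens. Tokens without any vowel or 'y' (which cannot carry
#' a syllable) are dropped, and sentences left with fewer than two words are
#' ignored, so every retained sentence has at least two countable words.
#'
#' @param cleaned A single cleaned text from [clean_text()].
#' @param doc_id Document identifier carried through the pipeline.
#' @return An object of class `tokenized_abstract`: a list with `doc_id` and
#'   `sentences` (a list of character vectors). Zero retained sentences mark
#'   the document unusable (see [is_scoreable()]).
#' @examples
#' segment("the cat sat. it purred loudly.", doc_id = "ex1")
#' @export
segment <- function(cleaned, doc_id = "doc") {
  stopifnot(is.character(cleaned), length(cleaned) == 1L)
  sents <- strsplit(cleaned, ".", fixed = TRUE)[[1L]]
  toks <- lapply(sents, function(s) {
    t <- tolower(strsplit(trimws(s), "\\s+")[[1L]])
    t <- t[nzchar(t)]
    t[grepl("[aeiouy]", t)]
  })
  toks <- toks[lengths(toks) >= 2L]
  structure(list(doc_id = doc_id, sentences = toks),
            class = "tokenized_abstract")
}

#' @export
print.tokenized_abstract <- function(x, ...) {
  cat("<tokenized_abstract>", x$doc_id, "-", length(x$sentences),
      "sentence(s),", sum(lengths(x$sentences)), "token(s)\n")
  invisible(x)
}

#' Is a tokenized abstract scoreable?
#'
#' A document is scoreable when at least one sentence (of two or more words)
#' survived cleaning and segmentation.
#'
#' @param tok A `tokenized_abstract`.
#' @return Logical scalar.
#' @export
is_scoreable <- function(tok) {
  stopifnot(inherits(tok, "tokenized_abstract"))
  length(tok$sentences) >= 1L
}
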