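#' Bundled resources
#'
#' The package ships small plain-text resources under `inst/extdata`. The
#' common-word list and jargon list are *synthetic stand-ins*, constructed for
#' this package, for the 2,949-word New Dale-Chall (NDC) common-word list and
#' the 2,138-word general-scientific-jargon list used in the original
#' abstract-readability study: the originals are not redistributable here, so
#' deterministic, clearly labelled substitutes with the same shape (size,
#' casing, one word per line) are bundled instead. Absolute scores computed
#' against the stand-in common-word list are therefore not comparable with
#' scores computed against the genuine NDC list, but every structural and
#' trend property of the pipeline is.
#'
#' @name resources
NULL

sci_extdata <- function(file) {
  system.file("extdata", file, package = "scireadability", mustWork = TRUE)
}

#' NDC common-word list (bundled synthetic stand-in)
#'
#' Returns the bundled 2,949-word common-word list used as the default
#' "familiar word" list for the New Dale-Chall score. Tokens absent from this
#' list count as difficult words.
#'
#' @return A [word_list()] of 2,949 lowercase words.
#' @export
ndc_common_words <- function() {
  suppressMessages(read_word_list(
    sci_extdata("ndc_common_synthetic.txt"),
    name = "ndc_common_synthetic",
    provenance = "bundled synthetic stand-in for the 2,949-word NDC common-word list"
  ))
}

#' General scientific jargon list (bundled synthetic stand-in)
#'
#' A hand-curated list of field-neutral scientific phrasing ("science-ese":
#' e.g. "moreover", "robust", "endogenous"), disjoint from the bundled
#' common-word list. Stands in for the study's manually rated 2,138-word
#' jargon list, which is consumed as a fixture, never derived automatically.
#'
#' @return A [word_list()].
#' @export
science_jargon_words <- function() {
  suppressMessages(read_word_list(
    sci_extdata("science_jargon_synthetic.txt"),
    name = "science_jargon_synthetic",
    provenance = "bundled synthetic stand-in for the manually curated general scientific jargon list"
  ))
}

#' Read a syllable dictionary
#'
#' The syllable dictionary maps lowercase words to one or more syllable
#' counts, overriding the vowel-run fallback of [count_syllables()]. Format:
#' one entry per line, `word<TAB>count[,count...]`. When a word has several
#' counts the counter uses the largest. The bundled dictionary is a
#' hand-curated exception table (silent final e, words whose only vowel
#' letter is 'y', common multi-count words); it is a synthetic, versioned
#' stand-in for a full pronouncing dictionary.
#'
#' @param path Path to a dictionary file; defaults to the bundled table.
#' @return An object of class `syllable_dict`: a data frame with columns
#'   `word`, `counts` (list of integer vectors) and `max_count`.
#' @export
syllable_dictionary <- function(path = sci_extdata("syllable_dict_synthetic.tsv")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed syllable dictionary line: '",
         lines[lengths(parts) != 2L][1L], "'")
  }
  word <- vapply(parts, `[[`, character(1), 1L)
  counts <- lapply(parts, function(p) {
    as.integer(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]])
  })
  if (any(vapply(counts, function(k) any(is.na(k)) || any(k < 1L), logical(1)))) {
    stop("syllable counts must be positive integers")
  }
  if (anyDuplicated(word)) {
    stop("duplicate words in syllable dictionary: ",
         paste(unique(word[duplicated(word)]), collapse = ", "))
  }
  structure(
    data.frame(
      word = tolower(word),
      max_count = vapply(counts, max, integer(1)),
      stringsAsFactors = FALSE
    ),
    counts = counts,
    class = c("syllable_dict", "data.frame")
  )
}

#' Default boilerplate phrases removed by the cleaning rules
#'
#' Phrases (matched case-insensitively) that mark trailing copyright or
#' funding boilerplate; everything from the first match to the end of the
#' abstract is stripped. Editable via the file interface of
#' [preprocess_rules()].
#'
#' @return Character vector of phrases.
#' @export
boilerplate_phrases <- function() {
  readLines(sci_extdata("boilerplate_phrases.txt"), encoding = "UTF-8", warn = FALSE)
}
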