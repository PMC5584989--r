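#' Create a word list
#'
#' A `word_list` is a named, ordered set of unique lowercase words with a
#' free-text provenance note. Word lists drive the New Dale-Chall difficult
#' word definition (a token is *difficult* when absent from the common-word
#' list), the derived science-specific common-word list, and jargon coverage
#' summaries. Entries must be alphabetic; apostrophes are permitted. For
#' derived lists the order is the derivation rank order.
#'
#' @param words Character vector. Lowercased on ingestion; duplicates are
#'   dropped keeping the first occurrence.
#' @param name Short label for the list.
#' @param provenance Free-text description of where the list came from.
#' @return An object of class `word_list` with elements `name`, `words`,
#'   `provenance`.
#' @examples
#' word_list(c("The", "the", "and"), name = "tiny")
#' @export
word_list <- function(words, name = "wordlist", provenance = "") {
  stopifnot(is.character(words), length(name) == 1L)
  words <- tolower(trimws(words))
  words <- words[nzchar(words)]
  bad <- words[!grepl("^[a-z']+$", words)]
  if (length(bad) > 0L) {
    stop("word list entries must be lowercase alphabetic (apostrophes allowed); ",
         "offending entries: ", paste(utils::head(unique(bad), 5L), collapse = ", "))
  }
  words <- words[!duplicated(words)]
  structure(
    list(name = name, words = words, provenance = provenance),
    class = "word_list"
  )
}

#' @export
length.word_list <- function(x) length(x$words)

#' @export
as.character.word_list <- function(x, ...) x$words

#' @export
print.word_list <- function(x, ...) {
  cat("<word_list>", x$name, "-", length(x$words), "words\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  cat("  head:", paste(utils::head(x$words, 8L), collapse = ", "), "\n")
  invisible(x)
}

#' Read a word list from a plain-text file
#'
#' One word per line; blank lines and lines starting with `#` are ignored.
#' Tokens are lowercased and de-duplicated preserving first occurrence.
#'
#' @param path Path to the file.
#' @param name Label for the list; defaults to the file name.
#' @param provenance Provenance note; defaults to the path.
#' @return A [word_list()].
#' @export
read_word_list <- function(path, name = basename(path), provenance = path) {
  if (!file.exists(path)) stop("word list file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (any(grepl("\\s", lines))) {
    stop("word list tokens must not contain whitespace; first offender: '",
         lines[grepl("\\s", lines)][1L], "' in ", path)
  }
  if (length(lines) == 0L) {
    warning("empty word list read from ", path)
    return(word_list(character(0), name = name, provenance = provenance))
  }
  wl <- word_list(lines, name = name, provenance = provenance)
  message("read ", length(wl$words), " words from ", path)
  wl
}

#' Write a word list to a plain-text file
#'
#' Inverse of [read_word_list()]: one word per line in list order.
#'
#' @param wl A [word_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_word_list <- function(wl, path) {
  stopifnot(inherits(wl, "word_list"))
  writeLines(wl$words, path)
  invisible(path)
}
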