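#' Configuration for deriving a science-specific common-word list
#'
#' The derivation samples a fixed number of documents from each publication
#' stratum (decade bins by default, to avoid recency bias), counts token
#' frequencies over the sample, removes words on the exclusion list (the NDC
#' common-word list), and keeps the `k` most frequent remaining words. `k`
#' defaults to 2,949 — the length of the NDC common-word list — so the
#' derived science vocabulary and the familiar-word list are comparable in
#' size.
#'
#' @param strata List of `c(start_year, end_year)` bins; default six decade
#'   bins 1960-2019. Must not overlap.
#' @param n_per_stratum Documents sampled per bin (default 2,000).
#' @param k Length of the derived list (default 2,949).
#' @param exclusion [word_list()] of words to exclude (default the bundled
#'   common-word list).
#' @param seed Random seed for the document sample.
#' @return A list of class `derivation_config`.
#' @export
derivation_config <- function(strata = lapply(0:5, function(d) c(1960, 1969) + 10 * d),
                              n_per_stratum = 2000L, k = 2949L,
                              exclusion = ndc_common_words(), seed = 1L) {
  stopifnot(k >= 1L, n_per_stratum >= 1L, length(strata) >= 1L,
            inherits(exclusion, "word_list"))
  bounds <- do.call(rbind, strata)
  if (any(bounds[, 1L] > bounds[, 2L])) stop("stratum with start > end")
  o <- order(bounds[, 1L])
  if (any(bounds[o, 1L][-1L] <= bounds[o, 2L][-length(strata)])) {
    stop("strata must not overlap")
  }
  structure(
    list(strata = strata, n_per_stratum = as.integer(n_per_stratum),
         k = as.integer(k), exclusion = exclusion, seed = as.integer(seed)),
    class = "derivation_config"
  )
}

# flat token stream for a set of records: list(tokens, doc_of_token)
corpus_tokens <- function(records, preprocess = TRUE, rules = preprocess_rules()) {
  text <- if (preprocess) clean_text(records$text, rules = rules) else records$text
  sent_split <- strsplit(tolower(text), ".", fixed = TRUE)
  all_sent <- unlist(sent_split, use.names = FALSE)
  doc_of_sent <- rep.int(seq_len(nrow(records)), lengths(sent_split))
  tok_split <- strsplit(trimws(all_sent), "\\s+")
  tok <- unlist(tok_split, use.names = FALSE)
  sent_of_tok <- rep.int(seq_along(all_sent), lengths(tok_split))
  ok <- nzchar(tok) & grepl("[aeiouy]", tok)
  tok <- tok[ok]
  sent_of_tok <- sent_of_tok[ok]
  sent_size <- tabulate(sent_of_tok, nbins = length(all_sent))
  keep <- sent_size[sent_of_tok] >= 2L
  list(tokens = tok[keep], doc = doc_of_sent[sent_of_tok[keep]])
}

#' Derive a science-specific common-word list from a corpus
#'
#' Samples `n_per_stratum` documents per stratum without replacement,
#' tokenizes them with the standard preprocessing, counts token frequencies
#' over the whole sample, removes exclusion-list words, and returns the `k`
#' most frequent remaining words in rank order (frequency ties broken
#' alphabetically, for determinism). The sampled document ids are recorded
#' in the derivation report so they can be excluded from all further
#' analysis.
#'
#' @param records Abstract records tibble (`doc_id`, `year`, `text`).
#' @param cfg A [derivation_config()].
#' @param preprocess Apply cleaning rules before tokenizing?
#' @return A [word_list()] whose `derivation_report` attribute records the
#'   seed, strata, `k` and sampled doc_ids.
#' @export
derive_science_common_words <- function(records, cfg = derivation_config(),
                                        preprocess = TRUE) {
  stopifnot(inherits(cfg, "derivation_config"),
            all(c("doc_id", "year", "text") %in% names(records)))
  sampled_idx <- withr::with_seed(cfg$seed, {
    unlist(lapply(cfg$strata, function(b) {
      in_bin <- which(records$year >= b[1L] & records$year <= b[2L])
      if (length(in_bin) < cfg$n_per_stratum) {
        stop("stratum ", b[1L], "-", b[2L], " has only ", length(in_bin),
             " document(s); ", cfg$n_per_stratum, " required", call. = FALSE)
      }
      sample(in_bin, cfg$n_per_stratum)
    }))
  })
  toks <- corpus_tokens(records[sampled_idx, , drop = FALSE],
                        preprocess = preprocess)
  freq <- table(toks$tokens)
  freq <- freq[!(names(freq) %in% cfg$exclusion$words)]
  ord <- order(-as.integer(freq), names(freq))
  ranked <- names(freq)[ord]
  k <- cfg$k
  if (k > length(ranked)) {
    warning("k = ", k, " exceeds available vocabulary (", length(ranked),
            "); returning the full ranked vocabulary")
    k <- length(ranked)
  }
  wl <- word_list(ranked[seq_len(k)], name = "science_common_derived",
                  provenance = sprintf(
                    "derived: top %d non-excluded words from %d sampled documents, seed %d",
                    k, length(sampled_idx), cfg$seed))
  attr(wl, "derivation_report") <- list(
    seed = cfg$seed,
    strata = cfg$strata,
    n_per_stratum = cfg$n_per_stratum,
    k = k,
    sampled_doc_ids = records$doc_id[sampled_idx]
  )
  wl
}

#' Write a derivation report
#'
#' Serialises the `derivation_report` attribute of a derived word list
#' (seed, strata, k, sampled doc_ids) as JSON so the sampled documents can
#' be excluded downstream and the derivation reproduced.
#'
#' @param wl A derived [word_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_derivation_report <- function(wl, path) {
  rep <- attr(wl, "derivation_report")
  if (is.null(rep)) stop("word list carries no derivation report")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Overlap of a derived list with an independent verification list
#'
#' Fraction of the derived list's words present in a verification list
#' derived the same way from an independent document sample. The original
#' study reports 90.95% for its science-specific common-word list.
#'
#' @param derived,verification [word_list()]s.
#' @return Fraction in `[0, 1]`.
#' @export
verification_overlap <- function(derived, verification) {
  stopifnot(inherits(derived, "word_list"), inherits(verification, "word_list"))
  if (length(derived$words) == 0L) stop("derived word list is empty")
  length(intersect(derived$words, verification$words)) / length(derived$words)
}

#' Percentage of an abstract's tokens covered by a word list
#'
#' Token-level coverage: each occurrence counts.
#'
#' @param tok A [segment()]ed abstract.
#' @param wl A [word_list()].
#' @return Percentage in `[0, 100]`, or `NA` with a warning for a tokenless
#'   document.
#' @export
list_coverage <- function(tok, wl) {
  stopifnot(inherits(tok, "tokenized_abstract"), inherits(wl, "word_list"))
  tokens <- unlist(tok$sentences, use.names = FALSE)
  if (length(tokens) == 0L) {
    warning("document ", tok$doc_id, " has no tokens; coverage undefined")
    return(NA_real_)
  }
  100 * sum(tokens %in% wl$words) / length(tokens)
}

#' Yearly mean word-list coverage over a corpus
#'
#' For each year with at least `min_n` usable abstracts, the mean over
#' abstracts of the token-level percentage covered by the list — the
#' quantity behind opposing common-word vs jargon coverage trends.
#'
#' @param records Abstract records tibble (`doc_id`, `year`, `text`).
#' @param wl A [word_list()].
#' @param min_n Minimum abstracts per year (default 10).
#' @param preprocess Apply cleaning rules?
#' @return Tibble with `year`, `n_abstracts`, `mean_coverage`.
#' @export
yearly_coverage <- function(records, wl, min_n = 10L, preprocess = TRUE) {
  toks <- corpus_tokens(records, preprocess = preprocess)
  n_tok <- tabulate(toks$doc, nbins = nrow(records))
  in_list <- toks$tokens %in% wl$words
  n_in <- tabulate(toks$doc[in_list], nbins = nrow(records))
  usable <- n_tok > 0L
  cov <- 100 * n_in[usable] / n_tok[usable]
  agg <- stats::aggregate(cov, list(year = records$year[usable]),
                          function(v) c(n = length(v), mean = mean(v)))
  out <- tibble::tibble(
    year = agg$year,
    n_abstracts = as.integer(agg$x[, "n"]),
    mean_coverage = unname(agg$x[, "mean"])
  )
  out[out$n_abstracts >= min_n, ]
}

#' Yearly trend of a single word's per-abstract frequency
#'
#' For each year with at least `min_n` abstracts, the mean over abstracts of
#' `100 * occurrences / tokens`. A word used nowhere yields an all-zero
#' series, which is valid.
#'
#' @param records Abstract records tibble.
#' @param word A single lowercase word.
#' @param min_n Minimum abstracts per year (default 10).
#' @param preprocess Apply cleaning rules?
#' @return Tibble with `year`, `n_abstracts`, `mean_pct`.
#' @export
word_frequency_trend <- function(records, word, min_n = 10L, preprocess = TRUE) {
  stopifnot(is.character(word), length(word) == 1L, word == tolower(word))
  toks <- corpus_tokens(records, preprocess = preprocess)
  n_tok <- tabulate(toks$doc, nbins = nrow(records))
  hits <- tabulate(toks$doc[toks$tokens == word], nbins = nrow(records))
  usable <- n_tok > 0L
  pct <- 100 * hits[usable] / n_tok[usable]
  agg <- stats::aggregate(pct, list(year = records$year[usable]),
                          function(v) c(n = length(v), mean = mean(v)))
  out <- tibble::tibble(
    year = agg$year,
    n_abstracts = as.integer(agg$x[, "n"]),
    mean_pct = unname(agg$x[, "mean"])
  )
  out[out$n_abstracts >= min_n, ]
}
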