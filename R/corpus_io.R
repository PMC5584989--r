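#' Read abstract records from a file
#'
#' Two dialects are supported. `"table"` is UTF-8, tab-separated with a
#' header row and columns `doc_id`, `journal`, `year`, `n_authors`, `text`;
#' tabs are unambiguous with free-text abstracts containing commas. A
#' missing `n_authors` is encoded as an empty field and surfaced as `NA`.
#' `"medline"` is a MEDLINE-like flat file with `TAG - value` lines
#' (continuation lines indented), records separated by blank lines; the
#' fields used are `PMID` (doc_id), `JT` (journal), `DP` (date; the first
#' four-digit year is taken, and multi-year strings such as "1998-1999" are
#' resolved to the first year with a log message), `AB` (abstract) and `AU`
#' (one line per author, counted).
#'
#' Records with an empty abstract are skipped with a logged count.
#'
#' @param path Input file path.
#' @param format `"table"` or `"medline"`.
#' @return A tibble of abstract records: `doc_id` (character), `journal`,
#'   `year` (integer), `n_authors` (integer, `NA` when missing), `text`.
#' @export
read_abstract_records <- function(path, format = c("table", "medline")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  recs <- switch(format,
    table = read_records_table(path),
    medline = read_records_medline(path)
  )
  empty <- is.na(recs$text) | !nzchar(trimws(recs$text))
  if (any(empty)) {
    message("skipped ", sum(empty), " record(s) with empty abstract text")
    recs <- recs[!empty, , drop = FALSE]
  }
  dup <- unique(recs$doc_id[duplicated(recs$doc_id)])
  if (length(dup) > 0L) {
    stop("duplicate doc_id(s): ", paste(utils::head(dup, 10L), collapse = ", "))
  }
  bad_year <- !is.na(recs$year) & (recs$year < 1800L | recs$year > 2100L)
  if (any(bad_year)) {
    warning(sum(bad_year), " record(s) with implausible year outside [1800, 2100]")
  }
  tibble::as_tibble(recs)
}

read_records_table <- function(path) {
  df <- tryCatch(
    readr::read_tsv(
      path,
      col_types = readr::cols(
        doc_id = readr::col_character(),
        journal = readr::col_character(),
        year = readr::col_character(),
        n_authors = readr::col_integer(),
        text = readr::col_character()
      ),
      progress = FALSE
    ),
    error = function(e) stop("unparseable table file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- c("doc_id", "journal", "year", "n_authors", "text")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("table file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  prob <- readr::problems(df)
  if (nrow(prob) > 0L) {
    stop("unparseable table file ", path, ": first problem at line ",
         prob$row[1L] + 1L, " (", prob$expected[1L], ")")
  }
  df$year <- parse_year(df$year)
  df[need]
}

read_records_medline <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # split into records at blank lines
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, blank[-length(blank)])) * !blank
  recs <- split(lines[!blank], grp[!blank])
  parsed <- lapply(seq_along(recs), function(i) {
    rl <- recs[[i]]
    is_cont <- grepl("^\\s", rl)
    tag <- ifelse(is_cont, NA, trimws(substr(rl, 1L, 4L)))
    val <- ifelse(is_cont, trimws(rl), trimws(sub("^.{4}-\\s*", "", rl)))
    bad <- !is_cont & !grepl("^[A-Z0-9]{1,4}\\s*-", rl)
    if (any(bad)) {
      stop("unparseable MEDLINE record ", i, ": offending line '",
           rl[bad][1L], "'", call. = FALSE)
    }
    # attach continuations to the preceding tag
    tag <- vapply(seq_along(tag), function(j) {
      k <- j
      while (is.na(tag[k])) k <- k - 1L
      tag[k]
    }, character(1))
    field <- function(t) {
      v <- val[tag == t]
      if (length(v) == 0L) NA_character_ else paste(v, collapse = " ")
    }
    list(
      doc_id = field("PMID"),
      journal = field("JT"),
      dp = field("DP"),
      n_authors = sum(tag == "AU" & !is_cont),
      text = field("AB")
    )
  })
  data.frame(
    doc_id = vapply(parsed, `[[`, character(1), "doc_id"),
    journal = vapply(parsed, `[[`, character(1), "journal"),
    year = parse_year(vapply(parsed, `[[`, character(1), "dp")),
    n_authors = vapply(parsed, function(p) {
      if (p$n_authors == 0L) NA_integer_ else as.integer(p$n_authors)
    }, integer(1)),
    text = vapply(parsed, `[[`, character(1), "text"),
    stringsAsFactors = FALSE
  )
}

# first four-digit year in a date string; logs non-trivial resolutions
parse_year <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexpr("(18|19|20|21)[0-9]{2}", x))
  out <- rep(NA_integer_, length(x))
  hit <- regexpr("(18|19|20|21)[0-9]{2}", x) > 0L
  out[hit] <- as.integer(m)
  fuzzy <- hit & !is.na(x) & trimws(x) != as.character(out)
  if (any(fuzzy)) {
    message("resolved ", sum(fuzzy),
            " date string(s) to their first four-digit year")
  }
  if (any(!hit & !is.na(x))) {
    stop("no four-digit year in date string(s): ",
         paste(utils::head(x[!hit & !is.na(x)], 5L), collapse = ", "))
  }
  out
}

#' Write abstract records to the tab-separated dialect
#'
#' @param records Tibble with `doc_id`, `journal`, `year`, `n_authors`,
#'   `text`. Embedded tabs/newlines in text are replaced by spaces.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abstract_records <- function(records, path) {
  need <- c("doc_id", "journal", "year", "n_authors", "text")
  stopifnot(all(need %in% names(records)))
  out <- records[need]
  out$text <- gsub("[\t\r\n]+", " ", out$text)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a per-document readability score table
#'
#' Writes the score table as tab-separated text with a documented column
#' order. Numeric columns are written with 17 significant digits so that
#' [read_scores_table()] reproduces every value bit-identically.
#'
#' @param scores Score tibble from [score_corpus()].
#' @param path Output path.
#' @param records Optional abstract records; when supplied, their `doc_id`s
#'   must align with `scores` (same ids, same order) or an error is raised.
#' @return `path`, invisibly.
#' @export
write_scores_table <- function(scores, path, records = NULL) {
  stopifnot(is.data.frame(scores), "doc_id" %in% names(scores))
  if (!is.null(records) && !identical(as.character(records$doc_id),
                                      as.character(scores$doc_id))) {
    stop("records and scores are misaligned: doc_id mismatch")
  }
  out <- scores
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  })
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a readability score table written by [write_scores_table()]
#'
#' @param path Input path.
#' @return A tibble with the stored columns; numeric fields restored to full
#'   precision.
#' @export
read_scores_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), na = "NA", progress = FALSE)
  # convert numerics through strtod (correctly rounded, unlike fast parsers)
  for (col in setdiff(names(df), c("doc_id", "journal"))) {
    v <- df[[col]]
    if (all(is.na(v) | grepl("^[-+0-9.eEIinNfFaA]+$", v))) {
      num <- suppressWarnings(as.numeric(v))
      if (!any(is.na(num) & !is.na(v))) {
        int <- suppressWarnings(as.integer(v))
        df[[col]] <- if (identical(as.numeric(int), num)) int else num
      }
    }
    if (col == "scoreable") df[[col]] <- as.logical(df[[col]])
  }
  df
}
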