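#' Yearly summaries of readability scores and components
#'
#' Arithmetic means over scoreable abstracts for each year. Years with fewer
#' than `min_n` abstracts are excluded, matching the study's rule for trend
#' and density summaries.
#'
#' @param scores Score tibble from [score_corpus()] (needs `year`).
#' @param min_n Minimum abstracts per year (default 10).
#' @return Tibble ordered by year: `year`, `n_abstracts`, `mean_fre`,
#'   `mean_ndc`, `mean_spw`, `mean_wps`, `mean_pct_difficult`.
#' @export
yearly_summary <- function(scores, min_n = 10L) {
  stopifnot(all(c("year", "fre", "ndc", "scoreable") %in% names(scores)))
  s <- scores[scores$scoreable & !is.na(scores$year), ]
  if (nrow(s) == 0L) stop("no scoreable documents")
  out <- dplyr::summarise(
    dplyr::group_by(s, year = .data$year),
    n_abstracts = dplyr::n(),
    mean_fre = mean(.data$fre),
    mean_ndc = mean(.data$ndc),
    mean_spw = mean(.data$syllables_per_word),
    mean_wps = mean(.data$words_per_sentence),
    mean_pct_difficult = mean(.data$pct_difficult),
    .groups = "drop"
  )
  out <- out[out$n_abstracts >= min_n, ]
  if (nrow(out) == 0L) {
    stop("no year has at least ", min_n, " abstracts")
  }
  dplyr::arrange(out, .data$year)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Used both for yearly trend correlations (e.g. mean FRE against year) and
#' for paired per-document score correlations. The 95% confidence interval
#' comes from the Fisher z-transform; the p-value is two-sided.
#'
#' @param x,y Paired numeric series (at least 3 points, finite variance).
#' @return A list of class `trend_result`: `r`, `ci_low`, `ci_high`, `p`,
#'   `n`.
#' @export
pearson_trend <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired points")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  structure(
    list(r = unname(ct$estimate), ci_low = ct$conf.int[1L],
         ci_high = ct$conf.int[2L], p = ct$p.value, n = length(x)),
    class = "trend_result"
  )
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("r = %.3f, 95%% CI [%.3f, %.3f], p = %.3g, n = %d\n",
              x$r, x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' Paired per-document correlation between two score series
#'
#' Generic paired Pearson correlation aligned by `doc_id`; used for
#' abstract-versus-full-text score tables.
#'
#' @param scores_a,scores_b Data frames with `doc_id` and `score` columns.
#' @return A `trend_result` (see [pearson_trend()]).
#' @export
paired_correlation <- function(scores_a, scores_b) {
  stopifnot(all(c("doc_id", "score") %in% names(scores_a)),
            all(c("doc_id", "score") %in% names(scores_b)))
  if (!setequal(scores_a$doc_id, scores_b$doc_id) ||
      anyDuplicated(scores_a$doc_id) || anyDuplicated(scores_b$doc_id)) {
    stop("misaligned doc_ids between the two score tables")
  }
  i <- match(scores_a$doc_id, scores_b$doc_id)
  pearson_trend(scores_a$score, scores_b$score[i])
}

year_term <- function(scores, center_year) {
  if (center_year) scores$year - round(mean(scores$year)) else scores$year
}

#' Fit the M0/M1/M2 mixed-effects model ladder
#'
#' Fits, with maximum-likelihood estimation: M0, readability predicted by a
#' journal random intercept only; M1, M0 plus a fixed effect of year; M2,
#' M1 plus journal-specific random year slopes. Models are compared by AIC
#' and BIC (differences reported against the best model). The year
#' fixed-effect test uses Satterthwaite denominator degrees of freedom; its
#' 95% CI is Wald, `beta ± t(df, 0.975) · se`.
#'
#' By default year is centered at the corpus midpoint before fitting: this
#' is an exact reparameterisation (year slopes, AIC and BIC are unchanged)
#' that avoids the near-singular intercept-slope correlation raw calendar
#' years induce in the random-slope model. `center_year = FALSE` fits raw
#' year.
#'
#' @param scores Score tibble from [score_corpus()] (`journal`, `year`, and
#'   the response column).
#' @param response `"fre"` or `"ndc"`.
#' @param center_year Center year at the corpus midpoint? Default `TRUE`.
#' @return A list of class `model_ladder`: `models` (the fitted lme4/lmerTest
#'   objects), `table` (per-model AIC/BIC, dAIC/dBIC, year beta with CI, t,
#'   Satterthwaite df, p, n_obs), `best` (model id with lowest AIC),
#'   `response`, `degenerate` (TRUE when only one journal was available and
#'   the hierarchy collapsed).
#' @export
fit_mixed_models <- function(scores, response = c("fre", "ndc"),
                             center_year = TRUE) {
  response <- match.arg(response)
  d <- model_frame(scores, response)
  d$yr <- year_term(d, center_year)
  degenerate <- length(unique(d$journal)) < 2L
  if (degenerate) {
    warning("single journal: random-effect hierarchy is degenerate; ",
            "fitting year trend by ordinary least squares")
    m1 <- stats::lm(y ~ yr, data = d)
    tab <- ladder_table(list(M1 = m1), d)
    return(structure(list(models = list(M1 = m1), table = tab, best = "M1",
                          response = response, degenerate = TRUE),
                     class = "model_ladder"))
  }
  ctrl <- lme4::lmerControl(optimizer = "bobyqa")
  m0 <- lmerTest::lmer(y ~ 1 + (1 | journal), data = d, REML = FALSE,
                       control = ctrl)
  m1 <- lmerTest::lmer(y ~ yr + (1 | journal), data = d, REML = FALSE,
                       control = ctrl)
  m2 <- lmerTest::lmer(y ~ yr + (1 + yr | journal), data = d, REML = FALSE,
                       control = ctrl)
  if (lme4::isSingular(m2)) {
    warning("M2 fit is singular (random-slope variance near zero); ",
            "estimates returned, interpret the slope variance with care")
  }
  models <- list(M0 = m0, M1 = m1, M2 = m2)
  tab <- ladder_table(models, d)
  structure(
    list(models = models, table = tab,
         best = tab$model[which.min(tab$aic)], response = response,
         degenerate = FALSE),
    class = "model_ladder"
  )
}

model_frame <- function(scores, response, need_authors = FALSE) {
  cols <- c("journal", "year", response, "scoreable",
            if (need_authors) "n_authors")
  stopifnot(all(cols %in% names(scores)))
  d <- scores[scores$scoreable, ]
  d <- d[stats::complete.cases(d[c("journal", "year", response)]), ]
  data.frame(journal = factor(d$journal), year = d$year, y = d[[response]],
             n_authors = if (need_authors) d$n_authors else NA_integer_)
}

ladder_table <- function(models, d) {
  rows <- lapply(names(models), function(id) {
    m <- models[[id]]
    fx <- fixed_effect_row(m, "yr")
    tibble::tibble(
      model = id, aic = stats::AIC(m), bic = stats::BIC(m),
      beta = fx[["beta"]], ci_low = fx[["ci_low"]], ci_high = fx[["ci_high"]],
      t = fx[["t"]], df = fx[["df"]], p = fx[["p"]], n_obs = nrow(d)
    )
  })
  tab <- dplyr::bind_rows(rows)
  tab$daic <- tab$aic - min(tab$aic)
  tab$dbic <- tab$bic - min(tab$bic)
  tab
}

# beta/CI/t/df/p for one fixed effect; Satterthwaite df for lmerTest fits,
# residual df for lm (the documented fallback)
fixed_effect_row <- function(m, term) {
  cf <- stats::coef(summary(m))
  if (!(term %in% rownames(cf))) {
    return(c(beta = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             t = NA_real_, df = NA_real_, p = NA_real_))
  }
  est <- cf[term, "Estimate"]
  se <- cf[term, "Std. Error"]
  if ("df" %in% colnames(cf)) {
    df <- cf[term, "df"]
    p <- cf[term, "Pr(>|t|)"]
  } else {
    df <- stats::df.residual(m)
    p <- 2 * stats::pt(abs(est / se), df, lower.tail = FALSE)
  }
  tcrit <- stats::qt(0.975, df)
  c(beta = est, ci_low = est - tcrit * se, ci_high = est + tcrit * se,
    t = est / se, df = df, p = p)
}

#' @export
print.model_ladder <- function(x, ...) {
  cat("<model_ladder> response:", x$response,
      if (x$degenerate) "(degenerate: single journal)", "\n")
  print(as.data.frame(x$table), digits = 4)
  cat("best model by AIC:", x$best, "\n")
  invisible(x)
}

#' Per-journal year slopes from the random-slope model
#'
#' Journal-specific slopes are the fixed year effect plus each journal's
#' random-slope deviation (BLUP); intercepts likewise.
#'
#' @param ladder A `model_ladder` from [fit_mixed_models()], or a fitted
#'   random-slope merMod.
#' @return Tibble with `journal`, `intercept`, `slope`.
#' @export
journal_slopes <- function(ladder) {
  m <- if (inherits(ladder, "model_ladder")) ladder$models$M2 else ladder
  if (is.null(m) || !inherits(m, "merMod")) {
    stop("no random-slope model available")
  }
  re <- lme4::ranef(m)$journal
  if (!"yr" %in% names(re)) stop("model has no random year slopes")
  fx <- lme4::fixef(m)
  tibble::tibble(
    journal = rownames(re),
    intercept = unname(fx["(Intercept)"]) + re[["(Intercept)"]],
    slope = unname(fx["yr"]) + re[["yr"]]
  )
}

#' Author-count model (M2 plus a number-of-authors fixed effect)
#'
#' Identical to the random-slope model M2 but with the number of authors as
#' a second fixed effect, used to test whether growing author lists explain
#' the year trend. Records lacking author information are excluded with a
#' logged count; optionally the data are restricted to abstracts with 1-10
#' authors, since many-author abstracts may bias the fit.
#'
#' @param scores Score tibble (needs `n_authors`).
#' @param response `"fre"` or `"ndc"`.
#' @param subset_1_to_10 Restrict to 1-10 authors? Default `TRUE`.
#' @param center_year Center year at the corpus midpoint? Default `TRUE`.
#' @return A list of class `author_model`: `model`, `table` (one row per
#'   fixed effect: beta, CI, t, Satterthwaite df, p), `n_obs`,
#'   `n_missing_authors`, `subset_1_to_10`.
#' @export
author_effect_model <- function(scores, response = c("fre", "ndc"),
                                subset_1_to_10 = TRUE, center_year = TRUE) {
  response <- match.arg(response)
  d <- model_frame(scores, response, need_authors = TRUE)
  n_missing <- sum(is.na(d$n_authors))
  if (n_missing > 0L) {
    message("excluded ", n_missing, " record(s) lacking author information")
    d <- d[!is.na(d$n_authors), ]
  }
  if (subset_1_to_10) d <- d[d$n_authors >= 1L & d$n_authors <= 10L, ]
  if (nrow(d) == 0L) stop("no records with usable author counts")
  if (stats::var(d$n_authors) == 0) {
    stop("all author counts identical: author effect not estimable")
  }
  d$yr <- year_term(d, center_year)
  m <- lmerTest::lmer(y ~ yr + n_authors + (1 + yr | journal), data = d,
                      REML = FALSE,
                      control = lme4::lmerControl(optimizer = "bobyqa"))
  tab <- dplyr::bind_rows(lapply(c(year = "yr", authors = "n_authors"),
                                 function(t) {
    fx <- fixed_effect_row(m, t)
    tibble::tibble(beta = fx[["beta"]], ci_low = fx[["ci_low"]],
                   ci_high = fx[["ci_high"]], t = fx[["t"]], df = fx[["df"]],
                   p = fx[["p"]])
  }), .id = "term")
  structure(
    list(model = m, table = tab, n_obs = nrow(d),
         n_missing_authors = n_missing, subset_1_to_10 = subset_1_to_10,
         response = response),
    class = "author_model"
  )
}

#' @export
print.author_model <- function(x, ...) {
  cat("<author_model> response:", x$response,
      if (x$subset_1_to_10) "(1-10 author subset)", "- n =", x$n_obs, "\n")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Summarise per-journal slopes by research field
#'
#' Mean and standard error of the member-journal year slopes within each
#' field. Journals mapped to several fields contribute to each of them; a
#' single-journal field has an undefined SE, reported as `NA`.
#'
#' @param slopes Tibble from [journal_slopes()].
#' @param field_map Data frame with columns `journal`, `field` (one row per
#'   journal-field pair; multi-row per journal allowed).
#' @return Tibble with `field`, `n_journals`, `mean_slope`, `se_slope`,
#'   `journals` (comma-separated member journals).
#' @export
summarize_field_slopes <- function(slopes, field_map) {
  stopifnot(all(c("journal", "slope") %in% names(slopes)),
            all(c("journal", "field") %in% names(field_map)))
  missing <- setdiff(slopes$journal, field_map$journal)
  if (length(missing) > 0L) {
    stop("journal(s) absent from field map: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  joined <- merge(field_map, slopes, by = "journal")
  out <- dplyr::summarise(
    dplyr::group_by(joined, field = .data$field),
    n_journals = dplyr::n(),
    mean_slope = mean(.data$slope),
    se_slope = ifelse(dplyr::n() > 1L,
                      stats::sd(.data$slope) / sqrt(dplyr::n()), NA_real_),
    journals = paste(sort(.data$journal), collapse = ","),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$field)
}

#' Read a journal-to-field mapping file
#'
#' TSV with columns `journal`, `field`; a journal may appear in several
#' rows (one per field).
#'
#' @param path Input path.
#' @return Tibble with `journal`, `field`.
#' @export
read_field_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    journal = readr::col_character(), field = readr::col_character()
  ), progress = FALSE)
  if (!all(c("journal", "field") %in% names(df))) {
    stop("field map must have columns journal, field")
  }
  df
}
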