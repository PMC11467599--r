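#' Percentage with half-up rounding
#'
#' The single rounding convention used by every report table:
#' `100 * numerator / denominator`, rounded half-up (so 0.5 always rounds
#' away from zero, unlike banker's rounding) to the requested number of
#' decimal places.
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param decimals Decimal places (0, 1 or 2 in the shipped tables).
#' @return A number.
#' @examples
#' pct(112, 116, 1)  # 96.6
#' pct(30, 94, 0)    # 32
#' @export
pct <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("pct(): denominator must be positive")
  x <- 100 * numerator / denominator
  scale <- 10^decimals
  floor(x * scale + 0.5 + 1e-9) / scale
}

purpose_levels <- c("seeking_advice", "offering_advice",
                    "experience_sharing", "news")
burn_type_levels <- c("contact", "sunburn", "scald", "chemical", "steam",
                      "friction", "cold", "firework", "flame", "laser",
                      "unspecified")
injured_levels <- c("adult", "child", "pet", "unspecified")

#' Thread length and participation statistics
#'
#' Posts per thread and distinct users per thread: mean, sample standard
#' deviation, minimum, maximum. Posts with no author id are counted as
#' distinct singleton authors (forum scrapes occasionally lack usernames);
#' their number is recorded in the `n_anonymous` attribute.
#'
#' @param threads List of thread records.
#' @return A tibble with rows `posts_per_thread` and `users_per_thread`
#'   and columns `mean`, `sd`, `min`, `max`; attribute `n_anonymous`.
#' @export
thread_stats <- function(threads) {
  stopifnot(length(threads) > 0L)
  n_posts <- vapply(threads, function(th) length(th$posts), integer(1))
  n_anon <- 0L
  n_users <- vapply(threads, function(th) {
    authors <- vapply(th$posts, function(p) {
      a <- p$author
      if (is.null(a) || is.na(a) || !nzchar(a)) NA_character_ else a
    }, character(1))
    anon <- sum(is.na(authors))
    n_anon <<- n_anon + anon
    length(unique(authors[!is.na(authors)])) + anon
  }, integer(1))
  out <- tibble::tibble(
    metric = c("posts_per_thread", "users_per_thread"),
    mean = c(mean(n_posts), mean(n_users)),
    sd = c(stats::sd(n_posts), stats::sd(n_users)),
    min = c(min(n_posts), min(n_users)),
    max = c(max(n_posts), max(n_users)))
  attr(out, "n_anonymous") <- n_anon
  out
}

#' Tabulate conversation purpose labels
#'
#' One manual label per initial post/video/tweet: seeking advice, offering
#' advice, experience sharing, or broadcasting news.
#'
#' @param labels Character vector of purpose labels.
#' @param decimals Decimal places for percentages (default 1).
#' @return Tibble with one row per purpose category (all four always
#'   present): `purpose`, `count`, `percentage`.
#' @export
purpose_table <- function(labels, decimals = 1) {
  bad <- setdiff(unique(labels), purpose_levels)
  if (length(bad)) stop("unknown purpose labels: ", paste(bad, collapse = ", "))
  counts <- table(factor(labels, levels = purpose_levels))
  n <- length(labels)
  tibble::tibble(purpose = purpose_levels,
                 count = as.integer(counts),
                 percentage = if (n > 0) pct(as.integer(counts), n, decimals)
                              else rep(0, 4L))
}

#' Burn type x injured party crosstab with margins
#'
#' @param records Data frame with columns `burn_type` (contact, sunburn,
#'   scald, chemical, steam, friction, cold, firework, flame, laser,
#'   unspecified) and `injured` (adult, child, pet, unspecified).
#' @param decimals Decimal places for the row-total percentages (default 0,
#'   whole percent).
#' @return Tibble with one row per burn type plus a `total` row; columns
#'   per injured party, `total`, and `total_pct` (row total as a
#'   percentage of the grand total; `NA` when the table is empty).
#' @export
burn_crosstab <- function(records, decimals = 0) {
  bt <- factor(records$burn_type, levels = burn_type_levels)
  inj <- factor(records$injured, levels = injured_levels)
  if (anyNA(bt) || anyNA(inj)) stop("unknown burn_type or injured level")
  tab <- table(bt, inj)
  grand <- sum(tab)
  row_tot <- rowSums(tab)
  out <- tibble::tibble(burn_type = burn_type_levels)
  for (lev in injured_levels) out[[lev]] <- as.integer(tab[, lev])
  out$total <- as.integer(row_tot)
  out$total_pct <- if (grand > 0) unname(pct(row_tot, grand, decimals))
                   else NA_real_
  total_row <- tibble::tibble(burn_type = "total")
  for (lev in injured_levels) total_row[[lev]] <- as.integer(sum(tab[, lev]))
  total_row$total <- as.integer(grand)
  total_row$total_pct <- if (grand > 0) pct(grand, grand, decimals)
                         else NA_real_
  rbind(out, total_row)
}

#' Posts per calendar year
#'
#' @param timestamps Character or Date/POSIXct vector of post timestamps;
#'   character input is parsed as ISO dates/datetimes. Unparseable entries
#'   are excluded and counted in the `n_unparseable` attribute.
#' @param decimals Decimal places for percentages (default 2).
#' @return Tibble `year`, `count`, `percentage`, one row per calendar year
#'   in the observed range (zero-filled).
#' @export
yearly_counts <- function(timestamps, decimals = 2) {
  if (inherits(timestamps, "Date") || inherits(timestamps, "POSIXt")) {
    years <- as.integer(format(timestamps, "%Y"))
  } else {
    years <- suppressWarnings(
      as.integer(substr(trimws(as.character(timestamps)), 1L, 4L)))
    years[!grepl("^[0-9]{4}", trimws(as.character(timestamps)))] <- NA
  }
  n_bad <- sum(is.na(years))
  years <- years[!is.na(years)]
  if (length(years) == 0L) {
    out <- tibble::tibble(year = integer(), count = integer(),
                          percentage = numeric())
    attr(out, "n_unparseable") <- n_bad
    return(out)
  }
  rng <- seq(min(years), max(years))
  counts <- as.integer(table(factor(years, levels = rng)))
  out <- tibble::tibble(year = rng, count = counts,
                        percentage = pct(counts, length(years), decimals))
  attr(out, "n_unparseable") <- n_bad
  out
}

contains_term <- function(texts, term) {
  vapply(texts, function(tx) {
    !is.na(tx) && nzchar(tx) && any_term_matches(tolower(tx), term)
  }, logical(1), USE.NAMES = FALSE)
}

#' Per-term prevalence across text units
#'
#' For each term, the percentage of units (posts, comments, tweets) whose
#' raw text contains it — phrase semantics at word boundaries, matching the
#' query matcher.
#'
#' @param units Character vector of raw unit texts.
#' @param terms Character vector of (possibly multiword) lowercase terms.
#' @param decimals Decimal places (default 1).
#' @return Tibble `term`, `count`, `percentage`.
#' @export
term_prevalence <- function(units, terms, decimals = 1) {
  n <- length(units)
  counts <- vapply(terms, function(tm) sum(contains_term(units, tm)),
                   integer(1))
  tibble::tibble(term = terms, count = as.integer(unname(counts)),
                 percentage = if (n > 0) unname(pct(counts, n, decimals))
                              else rep(0, length(terms)))
}

#' Most frequent words in a token corpus
#'
#' @param corpus List of token vectors (preprocessed documents).
#' @param n Number of words to return (default 50).
#' @param exclusions Words to omit; defaults to the packaged stopword list,
#'   which includes pronouns.
#' @return Tibble `word`, `count`, count-descending with lexicographic
#'   tie-break.
#' @export
top_frequent_words <- function(corpus, n = 50,
                               exclusions = default_stopwords()) {
  tokens <- unlist(corpus, use.names = FALSE)
  tokens <- tokens[!(tokens %in% exclusions)]
  if (length(tokens) == 0L) {
    return(tibble::tibble(word = character(), count = integer()))
  }
  tab <- table(tokens)
  ord <- order(-as.integer(tab), names(tab))
  keep <- ord[seq_len(min(n, length(tab)))]
  tibble::tibble(word = names(tab)[keep], count = as.integer(tab[keep]))
}

#' Detect parent voices in user/channel descriptions
#'
#' Counts descriptions containing at least one parent/child descriptor
#' term (phrase semantics at word boundaries).
#'
#' @param descriptions Character vector of user or channel description
#'   texts (`NA`/empty counted as non-matching).
#' @param parent_terms Terms identifying a parent voice; defaults to the
#'   taxonomy's children category.
#' @param decimals Decimal places for the percentage (default 0).
#' @return List with `count` and `percentage`.
#' @export
parent_voice <- function(descriptions,
                         parent_terms = default_taxonomy()$children,
                         decimals = 0) {
  n <- length(descriptions)
  hit <- rep(FALSE, n)
  for (tm in parent_terms) hit <- hit | contains_term(descriptions, tm)
  count <- sum(hit)
  list(count = count,
       percentage = if (n > 0) pct(count, n, decimals) else 0)
}

#' Full descriptive characterization of a filtered corpus
#'
#' Bundles every descriptive analysis into one report: thread statistics,
#' the purpose table, the burn-type x injured-party crosstab, yearly post
#' counts, prevalence of the specific first-aid and food terms, the top-50
#' word list, and parent-voice counts from user descriptions. Purpose and
#' burn labels are inputs (gold labels or human coding), not model output.
#'
#' @param threads List of thread records.
#' @param purpose Character vector of per-thread purpose labels (optional).
#' @param burn_records Data frame of per-thread `burn_type`/`injured`
#'   labels (optional).
#' @param taxonomy A `search_taxonomy` for the term-prevalence panel.
#' @param stopwords Stopword list for the word-frequency panel.
#' @return A `characterization_report` list of tables.
#' @export
characterize_corpus <- function(threads, purpose = NULL, burn_records = NULL,
                                taxonomy = default_taxonomy(),
                                stopwords = default_stopwords()) {
  texts <- unlist(lapply(threads, function(th) {
    vapply(th$posts, function(p) {
      if (is.null(p$text) || is.na(p$text)) "" else p$text
    }, character(1))
  }), use.names = FALSE)
  stamps <- unlist(lapply(threads, function(th) {
    vapply(th$posts, function(p) {
      if (is.null(p$timestamp) || is.na(p$timestamp)) NA_character_
      else as.character(p$timestamp)
    }, character(1))
  }), use.names = FALSE)
  descriptions <- unlist(lapply(threads, function(th) {
    vapply(th$posts, function(p) {
      if (is.null(p$user_description)) NA_character_
      else as.character(p$user_description)
    }, character(1))
  }), use.names = FALSE)
  tokens <- preprocess_corpus(texts, stopwords = stopwords)
  report <- list(
    threads = thread_stats(threads),
    purpose = if (!is.null(purpose)) purpose_table(purpose),
    burn = if (!is.null(burn_records)) burn_crosstab(burn_records),
    yearly = yearly_counts(stamps),
    prevalence = term_prevalence(texts,
                                 c(taxonomy$fa_specific, taxonomy$fa_food)),
    top_words = top_frequent_words(tokens, n = 50, exclusions = stopwords),
    parents = parent_voice(descriptions, taxonomy$children),
    n_threads = length(threads), n_posts = length(texts))
  class(report) <- "characterization_report"
  report
}

#' @export
print.characterization_report <- function(x, ...) {
  cat(sprintf("<characterization_report: %d threads, %d posts>\n",
              x$n_threads, x$n_posts))
  cat(sprintf("  parent voices: %d (%s%%)\n", x$parents$count,
              format(x$parents$percentage)))
  invisible(x)
}

#' Write a characterization report as CSV files plus a JSON bundle
#'
#' One CSV per table (`threads.csv`, `purpose.csv`, `burn.csv`,
#' `yearly.csv`, `prevalence.csv`, `top_words.csv`) and a combined
#' `report.json`.
#'
#' @param report A `characterization_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_characterization <- function(report, dir) {
  stopifnot(inherits(report, "characterization_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("threads", "purpose", "burn", "yearly", "prevalence",
               "top_words")) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
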