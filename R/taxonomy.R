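#' Search-term taxonomy for burn first aid conversations
#'
#' The packaged taxonomy groups lowercase search terms into six categories:
#' burn-injury terms, three flavours of first-aid terms (general advice
#' words, specific remedies, food-based remedies), child-reference terms
#' (used on platforms not already parent-specific), and exclusion terms that
#' weed out figurative uses such as burning calories or burning bridges.
#'
#' @param categories Named list of character vectors. All six category names
#'   (`burn_injury`, `fa_general`, `fa_specific`, `fa_food`, `children`,
#'   `exclusion`) must be present; terms must be nonempty, lowercase and
#'   unique within a category.
#' @return An object of class `search_taxonomy` (a named list of character
#'   vectors).
#' @export
search_taxonomy <- function(categories) {
  required <- c("burn_injury", "fa_general", "fa_specific", "fa_food",
                "children", "exclusion")
  if (!is.list(categories) || !all(required %in% names(categories))) {
    stop("taxonomy must contain all six categories: ",
         paste(required, collapse = ", "))
  }
  categories <- categories[required]
  for (nm in required) {
    terms <- categories[[nm]]
    if (!is.character(terms) || length(terms) == 0) {
      stop("category '", nm, "' must be a nonempty character vector")
    }
    if (anyDuplicated(terms)) {
      stop("category '", nm, "' contains duplicate terms")
    }
    if (!identical(terms, tolower(terms))) {
      stop("category '", nm, "' contains non-lowercase terms")
    }
  }
  structure(categories, class = "search_taxonomy")
}

#' Default burn first aid search taxonomy
#'
#' Returns the taxonomy shipped with the package: 9 burn-injury terms,
#' 10 general first-aid terms, 25 specific remedy terms, 11 food terms,
#' 16 child-reference terms and 9 exclusion terms. The source list repeated
#' "lotion" in the specific remedies; it is stored once here since category
#' term sets are duplicate-free.
#'
#' @return A `search_taxonomy` object.
#' @examples
#' tax <- default_taxonomy()
#' lengths(tax)
#' @export
default_taxonomy <- function() {
  path <- system.file("extdata", "taxonomy.json", package = "convomine",
                      mustWork = TRUE)
  search_taxonomy(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @export
print.search_taxonomy <- function(x, ...) {
  cat("<search_taxonomy>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %3d terms: %s%s\n", nm, length(x[[nm]]),
                paste(utils::head(x[[nm]], 4), collapse = ", "),
                if (length(x[[nm]]) > 4) ", ..." else ""))
  }
  invisible(x)
}

#' Platform search/analysis profile
#'
#' Captures how one platform is searched and analysed: whether
#' child-reference and exclusion terms are attached to its queries (they are
#' only needed on platforms that are not parent-specific), the query
#' character budget its search backend imposes, and which text span is the
#' unit of relevance analysis.
#'
#' @param platform Platform identifier string (e.g. `"mumsnet"`).
#' @param include_children,include_exclusions Logical; attach the children
#'   group / exclusion terms to composed queries.
#' @param char_budget Maximum rendered query length, or `Inf` for unlimited.
#' @param analysis_unit One of `"title_plus_main_post"`, `"per_tweet"`,
#'   `"per_comment"`.
#' @param dialect Query rendering dialect, `"boolean"` (parenthesised OR
#'   groups joined by AND, `NOT (...)` exclusions) or `"minus"` (bare
#'   groups, `-term` exclusions).
#' @return A `platform_profile` object.
#' @export
platform_profile <- function(platform,
                             include_children = FALSE,
                             include_exclusions = FALSE,
                             char_budget = Inf,
                             analysis_unit = c("title_plus_main_post",
                                               "per_tweet", "per_comment"),
                             dialect = c("boolean", "minus")) {
  stopifnot(is.character(platform), length(platform) == 1L, nzchar(platform),
            is.numeric(char_budget), length(char_budget) == 1L,
            char_budget > 0)
  analysis_unit <- match.arg(analysis_unit)
  dialect <- match.arg(dialect)
  structure(list(platform = platform,
                 include_children = isTRUE(include_children),
                 include_exclusions = isTRUE(include_exclusions),
                 char_budget = char_budget,
                 analysis_unit = analysis_unit,
                 dialect = dialect),
            class = "platform_profile")
}

#' Built-in platform profiles
#'
#' `forum_profile()` models parent-specific discussion boards (Mumsnet,
#' Netmums, Reddit parenting boards): every voice is assumed to be a parent
#' or caregiver, so no child-reference terms and no exclusion terms are
#' attached; the analysis unit is the thread title plus main post.
#' `microblog_profile()` models a general-audience microblog: queries carry
#' a children group and exclusion terms and respect a 1024-character budget;
#' each tweet is its own analysis unit. `video_profile()` models a
#' video-comment platform analysed per comment.
#'
#' @param platform Platform identifier.
#' @param char_budget Query character budget (microblog default 1024).
#' @return A `platform_profile`.
#' @export
forum_profile <- function(platform = "mumsnet") {
  platform_profile(platform, include_children = FALSE,
                   include_exclusions = FALSE, char_budget = Inf,
                   analysis_unit = "title_plus_main_post",
                   dialect = "boolean")
}

#' @rdname forum_profile
#' @export
microblog_profile <- function(platform = "twitter", char_budget = 1024) {
  platform_profile(platform, include_children = TRUE,
                   include_exclusions = TRUE, char_budget = char_budget,
                   analysis_unit = "per_tweet", dialect = "minus")
}

#' @rdname forum_profile
#' @export
video_profile <- function(platform = "youtube") {
  platform_profile(platform, include_children = FALSE,
                   include_exclusions = FALSE, char_budget = Inf,
                   analysis_unit = "per_comment", dialect = "boolean")
}

new_query <- function(platform, required_groups, excluded_terms = character(),
                      char_budget = Inf, dialect = "boolean") {
  stopifnot(length(required_groups) >= 1L)
  structure(list(platform = platform,
                 required_groups = required_groups,
                 excluded_terms = excluded_terms,
                 char_budget = char_budget,
                 dialect = dialect),
            class = "convo_query")
}

#' @export
print.convo_query <- function(x, ...) {
  cat("<convo_query platform=", x$platform, ">\n", sep = "")
  cat(" ", render_query(x), "\n")
  invisible(x)
}

#' Compose platform search queries from the taxonomy
#'
#' Search backends limit the number of terms per query, so the taxonomy is
#' split into exactly three queries per platform, each conjoining the
#' burn-injury group with one of the three first-aid groups (general,
#' specific, food). On profiles that request them, a child-reference group
#' is added as a further conjunct and the exclusion terms are attached as
#' negations.
#'
#' @param taxonomy A `search_taxonomy`.
#' @param profile A `platform_profile`.
#' @return A list of 3 `convo_query` objects. Errors if any rendered query
#'   exceeds the profile's character budget (no silent truncation).
#' @examples
#' qs <- compose_queries(default_taxonomy(), microblog_profile())
#' render_query(qs[[1]])
#' @export
compose_queries <- function(taxonomy, profile) {
  stopifnot(inherits(taxonomy, "search_taxonomy"),
            inherits(profile, "platform_profile"))
  fa_cats <- c("fa_general", "fa_specific", "fa_food")
  queries <- lapply(fa_cats, function(fa) {
    groups <- list(burn_injury = taxonomy$burn_injury)
    groups[[fa]] <- taxonomy[[fa]]
    if (profile$include_children) groups$children <- taxonomy$children
    excl <- if (profile$include_exclusions) taxonomy$exclusion else character()
    new_query(profile$platform, groups, excl,
              char_budget = profile$char_budget, dialect = profile$dialect)
  })
  for (q in queries) {
    len <- nchar(render_query(q))
    if (len > q$char_budget) {
      stop(sprintf(
        "query %s+%s renders to %d characters, over the %s budget of %d",
        names(q$required_groups)[1], names(q$required_groups)[2],
        len, profile$platform, as.integer(q$char_budget)))
    }
  }
  queries
}

quote_term <- function(term) {
  ifelse(grepl(" ", term, fixed = TRUE), paste0('"', term, '"'), term)
}

#' Render a query as a boolean search string
#'
#' The `"boolean"` dialect writes parenthesised OR-groups joined by AND with
#' a trailing `NOT (...)` for exclusions; the `"minus"` dialect writes bare
#' parenthesised groups and prefixes each exclusion with `-`. Multiword
#' phrases are double-quoted in both dialects.
#'
#' @param query A `convo_query`.
#' @param dialect Override the query's stored dialect.
#' @return A single string.
#' @export
render_query <- function(query, dialect = query$dialect) {
  groups <- vapply(query$required_groups, function(terms) {
    paste0("(", paste(quote_term(terms), collapse = " OR "), ")")
  }, character(1))
  if (identical(dialect, "minus")) {
    out <- paste(groups, collapse = " ")
    if (length(query$excluded_terms)) {
      out <- paste(out,
                   paste0("-", quote_term(query$excluded_terms),
                          collapse = " "))
    }
  } else {
    out <- paste(groups, collapse = " AND ")
    if (length(query$excluded_terms)) {
      out <- paste0(out, " NOT (",
                    paste(quote_term(query$excluded_terms),
                          collapse = " OR "), ")")
    }
  }
  out
}

#' Parse a boolean-dialect query string back into term groups
#'
#' Inverse of [render_query()] for the `"boolean"` dialect; used to check
#' that rendering is lossless.
#'
#' @param string A rendered boolean query string.
#' @return A list with `required_groups` (list of character vectors) and
#'   `excluded_terms`.
#' @export
parse_query <- function(string) {
  excluded <- character()
  not_at <- regexpr(" NOT (", string, fixed = TRUE)
  if (not_at > 0) {
    excl_part <- substr(string, not_at + 6L, nchar(string) - 1L)
    excluded <- parse_group(excl_part)
    string <- substr(string, 1L, not_at - 1L)
  }
  parts <- strsplit(string, " AND ", fixed = TRUE)[[1]]
  groups <- lapply(parts, function(p) {
    parse_group(sub("\\)$", "", sub("^\\(", "", p)))
  })
  list(required_groups = groups, excluded_terms = excluded)
}

parse_group <- function(body) {
  terms <- strsplit(body, " OR ", fixed = TRUE)[[1]]
  gsub('^"|"$', "", terms)
}

term_regex <- function(term) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term)
  esc <- gsub(" ", "[[:space:]]+", esc, fixed = TRUE)
  paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])")
}

any_term_matches <- function(text, terms) {
  for (term in terms) {
    if (grepl(term_regex(term), text, perl = TRUE)) return(TRUE)
  }
  FALSE
}

#' Match raw text against a composed query
#'
#' Mirrors search-engine term semantics on raw (pre-lemmatisation) text:
#' matching is case-insensitive, terms match at word boundaries only (so
#' "yo" never matches inside "you" or "yoghurt"), and multiword terms match
#' as contiguous phrases across whitespace. A text matches when at least one
#' term from every required group occurs and no excluded term occurs.
#'
#' @param text A raw string (may contain emoji/punctuation).
#' @param query A `convo_query`.
#' @return `TRUE`/`FALSE`; empty or missing text is `FALSE`.
#' @examples
#' q <- compose_queries(default_taxonomy(), forum_profile())[[1]]
#' match_text("Burnt my hand on the iron, any remedy?", q)
#' @export
match_text <- function(text, query) {
  stopifnot(inherits(query, "convo_query"))
  if (is.null(text) || length(text) == 0L || is.na(text) || !nzchar(text)) {
    return(FALSE)
  }
  text <- tolower(text)
  if (length(query$excluded_terms) &&
      any_term_matches(text, query$excluded_terms)) {
    return(FALSE)
  }
  for (group in query$required_groups) {
    if (!any_term_matches(text, group)) return(FALSE)
  }
  TRUE
}

thread_texts <- function(thread) {
  texts <- vapply(thread$posts, function(p) {
    if (is.null(p$text) || is.na(p$text)) "" else p$text
  }, character(1))
  if (!is.null(thread$title) && !is.na(thread$title)) {
    texts <- c(thread$title, texts)
  }
  texts
}

#' Select whole conversation threads matching any query
#'
#' A thread is retained in full if any of its posts (or its title) matches
#' any of the supplied queries; results from the separate queries are merged
#' so each thread id appears at most once.
#'
#' @param threads List of thread records (each a list with `thread_id`,
#'   `platform`, optional `title`, and `posts`, a list of post records with
#'   a `text` field).
#' @param queries List of `convo_query` objects.
#' @return The retained subset of `threads`, duplicate-free, in input order.
#' @export
select_threads <- function(threads, queries) {
  ids <- vapply(threads, function(th) as.character(th$thread_id), character(1))
  if (anyDuplicated(ids)) stop("thread ids must be unique")
  keep <- vapply(threads, function(th) {
    texts <- thread_texts(th)
    for (q in queries) {
      for (txt in texts) {
        if (match_text(txt, q)) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  threads[keep]
}
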