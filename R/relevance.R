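#' Dual-lexicon relevance scoring of analysis units
#'
#' The core relevance filter scores a text unit against two expanded
#' lexicons: the mean over all (token, lexicon-term) pairs of cosine
#' similarity gives one score per polarity. A unit is relevant when it sits
#' close to the positive (burn first aid) lexicon and far from the negative
#' (figurative/distractor sense) lexicon under two per-platform thresholds.
#'
#' @name relevance
NULL

lexicon_matrix <- function(model, lexicon) {
  terms <- unique(unlist(strsplit(lexicon$terms, "[[:space:]]+")))
  v <- embedding_vectors(model, terms)
  v <- v[!apply(v, 1L, anyNA), , drop = FALSE]
  if (nrow(v) == 0L) stop("no lexicon term has an embedding vector")
  row_normalize(v)
}

new_relevance_score <- function(pos_mean, neg_mean, n_tokens) {
  structure(list(pos_mean = pos_mean, neg_mean = neg_mean,
                 n_tokens = as.integer(n_tokens),
                 defined = n_tokens > 0L),
            class = "relevance_score")
}

#' Score one token list against positive and negative lexicons
#'
#' `pos_mean` is the mean cosine similarity over all pairs of (unit token,
#' positive-lexicon term); `neg_mean` analogously for the negative lexicon.
#' Tokens without a vector (subword inference off or no known n-gram) are
#' skipped and do not count toward `n_tokens`; a unit with no scorable
#' token has `defined = FALSE`.
#'
#' @param tokens Character vector of preprocessed tokens.
#' @param pos,neg `expanded_lexicon` objects.
#' @param model An `embedding_model`.
#' @return A `relevance_score` with fields `pos_mean`, `neg_mean`,
#'   `n_tokens`, `defined`.
#' @export
score_unit <- function(tokens, pos, neg, model) {
  scores <- score_units(list(tokens), pos, neg, model)
  new_relevance_score(scores$pos_mean[1], scores$neg_mean[1],
                      scores$n_tokens[1])
}

#' Score many token lists at once (vectorised)
#'
#' Identical semantics to [score_unit()]; the pairwise mean is computed as
#' the mean over scorable tokens of the dot product with the mean
#' unit-normalised lexicon vector, which equals the mean over all pairs.
#'
#' @param token_lists List of token character vectors.
#' @inheritParams score_unit
#' @return A `tibble` with one row per unit: `pos_mean`, `neg_mean`,
#'   `n_tokens`, `defined`.
#' @export
score_units <- function(token_lists, pos, neg, model) {
  stopifnot(inherits(pos, "expanded_lexicon"),
            inherits(neg, "expanded_lexicon"),
            inherits(model, "embedding_model"))
  pos_mean_vec <- colMeans(lexicon_matrix(model, pos))
  neg_mean_vec <- colMeans(lexicon_matrix(model, neg))
  n <- length(token_lists)
  pm <- nm <- rep(NA_real_, n)
  nt <- integer(n)
  for (i in seq_len(n)) {
    toks <- token_lists[[i]]
    if (length(toks) == 0L) next
    v <- embedding_vectors(model, toks)
    v <- v[!apply(v, 1L, anyNA), , drop = FALSE]
    if (nrow(v) == 0L) next
    v <- row_normalize(v)
    nt[i] <- nrow(v)
    pm[i] <- mean(v %*% pos_mean_vec)
    nm[i] <- mean(v %*% neg_mean_vec)
  }
  tibble::tibble(pos_mean = pm, neg_mean = nm, n_tokens = nt,
                 defined = nt > 0L)
}

#' @export
print.relevance_score <- function(x, ...) {
  cat(sprintf("<relevance_score pos=%.4f neg=%.4f n=%d defined=%s>\n",
              x$pos_mean, x$neg_mean, x$n_tokens, x$defined))
  invisible(x)
}

#' Per-platform dual thresholds
#'
#' @param platform Platform id.
#' @param theta_pos Minimum positive-lexicon mean similarity (inclusive).
#' @param theta_neg Maximum negative-lexicon mean similarity (inclusive).
#' @param provenance Free-form record of how the pair was calibrated.
#' @return A `threshold_pair`.
#' @export
threshold_pair <- function(platform, theta_pos, theta_neg,
                           provenance = NULL) {
  stopifnot(is.finite(theta_pos), is.finite(theta_neg))
  structure(list(platform = platform, theta_pos = theta_pos,
                 theta_neg = theta_neg, provenance = provenance),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("<threshold_pair %s: theta_pos=%.4f theta_neg=%.4f>\n",
              x$platform, x$theta_pos, x$theta_neg))
  invisible(x)
}

#' Classify a scored unit as relevant or irrelevant
#'
#' Relevant iff `pos_mean >= theta_pos` and `neg_mean <= theta_neg`, both
#' boundaries inclusive. An undefined score (no scorable tokens) is an
#' error here; the pipeline-level filter treats such units as irrelevant.
#'
#' @param score A `relevance_score`.
#' @param thresholds A `threshold_pair`.
#' @return `"relevant"` or `"irrelevant"`.
#' @export
classify <- function(score, thresholds) {
  stopifnot(inherits(score, "relevance_score"),
            inherits(thresholds, "threshold_pair"))
  if (!isTRUE(score$defined)) {
    stop("cannot classify an undefined relevance score (no scorable tokens)")
  }
  if (score$pos_mean >= thresholds$theta_pos &&
      score$neg_mean <= thresholds$theta_neg) "relevant" else "irrelevant"
}

classify_scores <- function(scores, thresholds) {
  ok <- scores$defined &
    scores$pos_mean >= thresholds$theta_pos &
    scores$neg_mean <= thresholds$theta_neg
  ok & !is.na(ok)
}

f1_score <- function(tp, fp, fn) {
  denom <- 2 * tp + fp + fn
  ifelse(denom == 0, 0, 2 * tp / denom)
}

#' Calibrate dual thresholds against gold labels
#'
#' Exhaustive grid search over (theta_pos, theta_neg) pairs maximising an
#' objective on the relevant class (default F1). The grid spans the
#' observed score range at the requested resolution. Ties are broken
#' deterministically: smallest `theta_pos`, then largest `theta_neg`.
#'
#' @param scores A data frame from [score_units()] (columns `pos_mean`,
#'   `neg_mean`, `defined`).
#' @param gold Logical vector (or `"relevant"`/`"irrelevant"` factor) of
#'   gold labels, one per scored unit.
#' @param platform Platform id stored on the result.
#' @param objective `"f1"` (only built-in objective).
#' @param resolution Grid step on the similarity scale.
#' @return A `threshold_pair` whose `provenance` records the objective
#'   value achieved and the grid used.
#' @export
calibrate_thresholds <- function(scores, gold, platform = "synthetic",
                                 objective = "f1", resolution = 0.01) {
  if (is.character(gold) || is.factor(gold)) {
    gold <- as.character(gold) == "relevant"
  }
  stopifnot(length(gold) == nrow(scores), objective == "f1")
  if (length(unique(gold)) < 2L) {
    stop("calibration needs both relevant and irrelevant gold labels")
  }
  def <- scores$defined
  pos <- ifelse(def, scores$pos_mean, -Inf)   # undefined units never retained
  neg <- ifelse(def, scores$neg_mean, Inf)
  grid_p <- seq(floor(min(pos[def]) / resolution) * resolution,
                max(pos[def]) + resolution, by = resolution)
  grid_n <- seq(floor(min(neg[def]) / resolution) * resolution,
                max(neg[def]) + resolution, by = resolution)
  P <- outer(pos, grid_p, ">=")        # n x Gp
  N <- outer(neg, grid_n, "<=")        # n x Gn
  storage.mode(P) <- "numeric"
  storage.mode(N) <- "numeric"
  TP <- crossprod(P * gold, N)         # Gp x Gn
  PP <- crossprod(P, N)                # predicted positive
  n_gold <- sum(gold)
  F1 <- 2 * TP / (PP + n_gold)
  F1[is.nan(F1)] <- 0
  best <- max(F1)
  hits <- which(F1 >= best - 1e-12, arr.ind = TRUE)
  # smallest theta_pos, then largest theta_neg
  ord <- order(grid_p[hits[, 1]], -grid_n[hits[, 2]])
  pick <- hits[ord[1], ]
  threshold_pair(platform, grid_p[pick[1]], grid_n[pick[2]],
                 provenance = list(objective = objective, value = best,
                                   resolution = resolution,
                                   n_units = nrow(scores)))
}

analysis_units <- function(threads, profile, stopwords = default_stopwords()) {
  if (profile$analysis_unit == "title_plus_main_post") {
    texts <- vapply(threads, function(th) {
      main <- if (length(th$posts)) th$posts[[1]]$text else ""
      title <- if (is.null(th$title)) "" else th$title
      trimws(paste(title, main))
    }, character(1))
    list(texts = texts,
         unit_thread = seq_along(threads),
         unit_post = rep(NA_integer_, length(threads)))
  } else {
    # per_tweet / per_comment: every post is its own unit
    unit_thread <- integer(0); unit_post <- integer(0); texts <- character(0)
    for (i in seq_along(threads)) {
      posts <- threads[[i]]$posts
      texts <- c(texts, vapply(posts, function(p) {
        if (is.null(p$text) || is.na(p$text)) "" else p$text
      }, character(1)))
      unit_thread <- c(unit_thread, rep.int(i, length(posts)))
      unit_post <- c(unit_post, seq_along(posts))
    }
    list(texts = texts, unit_thread = unit_thread, unit_post = unit_post)
  }
}

#' Filter a thread corpus by dual-lexicon relevance
#'
#' Classifies each analysis unit of the profile's platform — thread title
#' plus main post for forums, each tweet or comment elsewhere — and retains
#' relevant content. Units with no scorable token are conservatively
#' classified irrelevant. For per-post units, a thread survives when at
#' least one of its posts is relevant; irrelevant posts are dropped from
#' surviving threads.
#'
#' @param threads List of thread records (see [select_threads()]).
#' @param profile A `platform_profile`.
#' @param pos,neg `expanded_lexicon` objects.
#' @param model An `embedding_model`.
#' @param thresholds A `threshold_pair`.
#' @param stopwords Stopword list for unit preprocessing.
#' @param reduction_decimals Decimal places for the reported percentage
#'   reduction (default 0, matching whole-percent reporting).
#' @return A list with `threads` (the retained corpus), `units` (a tibble
#'   of per-unit scores and classifications) and `report` (a
#'   `filter_report`: unit counts before/after and percentage reduction).
#' @export
filter_corpus <- function(threads, profile, pos, neg, model, thresholds,
                          stopwords = default_stopwords(),
                          reduction_decimals = 0) {
  stopifnot(inherits(profile, "platform_profile"))
  units <- analysis_units(threads, profile, stopwords)
  token_lists <- preprocess_corpus(units$texts, stopwords = stopwords)
  scores <- score_units(token_lists, pos, neg, model)
  relevant <- classify_scores(scores, thresholds)
  unit_tbl <- tibble::tibble(
    thread = units$unit_thread, post = units$unit_post,
    pos_mean = scores$pos_mean, neg_mean = scores$neg_mean,
    n_tokens = scores$n_tokens, defined = scores$defined,
    relevant = relevant)
  if (profile$analysis_unit == "title_plus_main_post") {
    retained <- threads[relevant]
  } else {
    keep_thread <- sort(unique(units$unit_thread[relevant]))
    retained <- lapply(keep_thread, function(i) {
      th <- threads[[i]]
      th$posts <- th$posts[units$unit_post[units$unit_thread == i & relevant]]
      th
    })
  }
  n_before <- length(units$texts)
  n_after <- sum(relevant)
  report <- filter_report(profile$platform, profile$analysis_unit,
                          n_before, n_after, reduction_decimals)
  list(threads = retained, units = unit_tbl, report = report)
}

#' Construct a filtering report
#'
#' @param platform Platform id.
#' @param unit Analysis unit name.
#' @param n_before,n_after Unit counts before and after filtering.
#' @param decimals Decimal places for the percentage reduction.
#' @return A `filter_report` list; `reduction_pct` is
#'   `100 * (1 - after/before)` rounded half-up.
#' @export
filter_report <- function(platform, unit, n_before, n_after, decimals = 0) {
  stopifnot(n_after <= n_before)
  reduction <- if (n_before == 0) 0 else {
    pct(n_before - n_after, n_before, decimals)
  }
  structure(list(platform = platform, unit = unit,
                 n_before = as.integer(n_before),
                 n_after = as.integer(n_after),
                 n_removed = as.integer(n_before - n_after),
                 reduction_pct = reduction),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report %s/%s: %d -> %d units (%s%% reduction)>\n",
              x$platform, x$unit, x$n_before, x$n_after,
              format(x$reduction_pct)), sep = "")
  invisible(x)
}

#' Build the default positive and negative relevance lexicons
#'
#' The positive lexicon seeds with the burn-injury and all first-aid terms
#' of the taxonomy and expands with their `k` nearest embedding
#' neighbours. The negative lexicon defaults to seeding with the exclusion
#' terms (`strategy = "exclusion"`); alternatively
#' (`strategy = "negated"`), its neighbours are the `k` vocabulary terms
#' closest to the negated positive-seed centroid — two readings of
#' "similar to the negated search terms", both shipped since neither is
#' canonical.
#'
#' @param model An `embedding_model`.
#' @param taxonomy A `search_taxonomy`.
#' @param k Neighbours to add per lexicon.
#' @param strategy Negative-lexicon construction, `"exclusion"` or
#'   `"negated"`.
#' @return List with elements `pos` and `neg` (`expanded_lexicon`s).
#' @export
relevance_lexicons <- function(model, taxonomy = default_taxonomy(), k = 50,
                               strategy = c("exclusion", "negated")) {
  strategy <- match.arg(strategy)
  # scoring happens in lemma space, so seed terms are lemmatized first
  # ("burns"/"burnt" -> "burn", "calories" -> "calorie")
  pos_seeds <- unique(lemmatize(unlist(strsplit(
    c(taxonomy$burn_injury, taxonomy$fa_general,
      taxonomy$fa_specific, taxonomy$fa_food), "[[:space:]]+"))))
  neg_seeds <- unique(lemmatize(taxonomy$exclusion))
  pos <- expand_lexicon(model, pos_seeds, k = k, polarity = "relevant")
  if (strategy == "exclusion") {
    neg <- expand_lexicon(model, neg_seeds, k = k,
                          polarity = "irrelevant")
  } else {
    seed_tokens <- unique(unlist(strsplit(pos_seeds, "[[:space:]]+")))
    sv <- embedding_vectors(model, seed_tokens)
    sv <- sv[!apply(sv, 1L, anyNA), , drop = FALSE]
    cen <- -colMeans(row_normalize(sv))
    cen <- cen / sqrt(sum(cen^2))
    vocab <- setdiff(rownames(model$vectors), c(pos_seeds, seed_tokens))
    cv <- row_normalize(model$vectors[vocab, , drop = FALSE])
    score <- drop(cv %*% cen)
    ord <- order(-score, vocab)
    neighbors <- vocab[ord][seq_len(min(k, length(vocab)))]
    neg <- structure(list(polarity = "irrelevant",
                          seeds = neg_seeds,
                          neighbors = setdiff(neighbors, neg_seeds),
                          terms = unique(c(neg_seeds, neighbors)),
                          aggregate = "negated_centroid", k = k),
                     class = "expanded_lexicon")
  }
  list(pos = pos, neg = neg)
}
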