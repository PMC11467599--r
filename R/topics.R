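#' Fit a fixed-K topic model
#'
#' Latent Dirichlet allocation with symmetric priors, fitted by collapsed
#' Gibbs sampling (single chain, single thread; deterministic under
#' `seed`). K is a configuration value — the pipeline default of 11 topics
#' per platform corpus is fixed up front, not selected from the data.
#' Posterior means are taken from the final sweep's count matrices:
#' `topic_word[k, w] = (n_kw + beta) / (n_k + V * beta)` and
#' `doc_topic[d, k] = (n_dk + alpha) / (n_d + K * alpha)`.
#'
#' @param docs List of token character vectors (one per document).
#' @param K Number of topics (default 11).
#' @param alpha Document-topic concentration (default `1/K`).
#' @param beta Topic-word concentration (default 0.01).
#' @param n_iter Gibbs sweeps (default 200).
#' @param seed Integer RNG seed.
#' @return A `topic_model`: list with `K`, `vocab`, `topic_word`
#'   (K x V, rows sum to 1), `doc_topic` (D x K, rows sum to 1),
#'   `doc_ids`, and the hyperparameters.
#' @export
fit_topics <- function(docs, K = 11, alpha = 1 / K, beta = 0.01,
                       n_iter = 200, seed = 1) {
  stopifnot(length(docs) > 0L, K >= 1)
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  if (length(vocab) == 0L) stop("empty vocabulary: no tokens in any document")
  idx <- seq_along(vocab)
  names(idx) <- vocab
  ids <- lapply(docs, function(d) as.integer(idx[d] - 1L))
  fit <- .lda_gibbs(ids, length(vocab), as.integer(K), alpha, beta,
                    as.integer(n_iter), as.integer(seed))
  n_kw <- fit$n_kw
  n_dk <- fit$n_dk
  topic_word <- (n_kw + beta) / (rowSums(n_kw) + length(vocab) * beta)
  doc_topic <- (n_dk + alpha) / (rowSums(n_dk) + K * alpha)
  colnames(topic_word) <- vocab
  doc_ids <- names(docs)
  if (is.null(doc_ids)) doc_ids <- as.character(seq_along(docs))
  rownames(doc_topic) <- doc_ids
  structure(list(K = as.integer(K), vocab = vocab,
                 topic_word = topic_word, doc_topic = doc_topic,
                 doc_ids = doc_ids,
                 hyperparameters = list(alpha = alpha, beta = beta,
                                        n_iter = n_iter),
                 seed = seed),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("<topic_model K=%d, |vocab|=%d, %d docs>\n",
              x$K, length(x$vocab), nrow(x$doc_topic)))
  for (k in seq_len(min(x$K, 5))) {
    cat(sprintf("  topic %d: %s\n", k,
                paste(top_words(x, k, 6), collapse = " ")))
  }
  invisible(x)
}

#' Assign a document to one or more topics
#'
#' A document belongs to every topic whose weight reaches the membership
#' threshold `tau` (inclusive); if none does, it belongs to its
#' highest-weight topic alone, with ties including all tied argmax topics.
#' Overlapping membership is deliberate — one discourse can span topics.
#'
#' @param model A `topic_model`.
#' @param doc Document id (name) or index.
#' @param tau Membership threshold in (0, 1]; default 0.25.
#' @return Integer vector of topic ids (1-based), sorted.
#' @export
assign_topics <- function(model, doc, tau = 0.25) {
  stopifnot(inherits(model, "topic_model"))
  if (is.character(doc)) {
    if (!doc %in% rownames(model$doc_topic)) stop("unknown document: ", doc)
    weights <- model$doc_topic[doc, ]
  } else {
    if (doc < 1L || doc > nrow(model$doc_topic)) {
      stop("unknown document index: ", doc)
    }
    weights <- model$doc_topic[doc, ]
  }
  hits <- which(weights >= tau)
  if (length(hits) == 0L) hits <- which(weights == max(weights))
  sort(unname(hits))
}

#' Multi-topic assignment for every document
#'
#' @param model A `topic_model`.
#' @param tau Membership threshold.
#' @return A `topic_assignment`: named list of integer topic-id vectors,
#'   one per document, with `tau` attached.
#' @export
assign_all_topics <- function(model, tau = 0.25) {
  sets <- lapply(seq_len(nrow(model$doc_topic)), assign_topics,
                 model = model, tau = tau)
  names(sets) <- model$doc_ids
  structure(list(sets = sets, tau = tau, K = model$K),
            class = "topic_assignment")
}

#' Top words of a topic
#'
#' @param model A `topic_model`.
#' @param topic Topic id (1-based).
#' @param n Number of words; if `n` exceeds the vocabulary the full ranking
#'   is returned.
#' @return Character vector of the `n` highest-probability terms,
#'   probability-descending with lexicographic tie-break.
#' @export
top_words <- function(model, topic, n = 10) {
  stopifnot(inherits(model, "topic_model"), topic >= 1, topic <= model$K)
  if (n <= 0) return(character())
  probs <- model$topic_word[topic, ]
  ord <- order(-probs, names(probs))
  model$vocab[ord][seq_len(min(n, length(probs)))]
}

#' Count documents assigned to both of two topics
#'
#' @param assignment A `topic_assignment`.
#' @param a,b Distinct topic ids.
#' @param total Denominator for the percentage (defaults to the number of
#'   assigned documents).
#' @return List with `count` and `percentage` (1 decimal, half-up).
#' @export
topic_overlap <- function(assignment, a, b, total = length(assignment$sets)) {
  stopifnot(inherits(assignment, "topic_assignment"), a != b)
  count <- sum(vapply(assignment$sets,
                      function(s) (a %in% s) && (b %in% s), logical(1)))
  list(count = count, percentage = pct(count, total, 1))
}

#' Percentage of documents assigned to more than one topic
#'
#' @param assignment A `topic_assignment`.
#' @param total Denominator (defaults to the number of documents).
#' @return Percentage, 2 decimals, half-up.
#' @export
multi_topic_rate <- function(assignment, total = length(assignment$sets)) {
  stopifnot(inherits(assignment, "topic_assignment"))
  pct(sum(lengths(assignment$sets) >= 2L), total, 2)
}

#' Pairwise topic-overlap matrix
#'
#' @param assignment A `topic_assignment`.
#' @return K x K integer matrix; entry (a, b) counts documents assigned to
#'   both topics, diagonal counts per-topic membership.
#' @export
overlap_matrix <- function(assignment) {
  K <- assignment$K
  m <- matrix(0L, K, K)
  for (s in assignment$sets) {
    m[s, s] <- m[s, s] + 1L
  }
  m
}

#' Match fitted topics to planted topics
#'
#' Finds the topic permutation maximising total top-`n` word recovery
#' between a fitted model and reference (planted) topic-word
#' distributions: exact search over permutations for K <= 8, greedy
#' maximum otherwise. Used to score topic recovery independently of label
#' order.
#'
#' @param model A `topic_model`.
#' @param reference K x V matrix of planted topic-word probabilities
#'   (colnames are terms).
#' @param n Top-word list length compared (default 10).
#' @return List with `permutation` (fitted topic matched to each reference
#'   topic) and `recovery` (per reference topic, the fraction of its top-n
#'   words present in the matched fitted topic's top-n).
#' @export
match_topics <- function(model, reference, n = 10) {
  K <- nrow(reference)
  stopifnot(K == model$K)
  ref_top <- lapply(seq_len(K), function(k) {
    p <- reference[k, ]
    colnames(reference)[order(-p, colnames(reference))][seq_len(min(n, ncol(reference)))]
  })
  fit_top <- lapply(seq_len(K), top_words, model = model, n = n)
  score <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      score[i, j] <- length(intersect(ref_top[[i]], fit_top[[j]])) /
        length(ref_top[[i]])
    }
  }
  if (K <= 8) {
    perms <- all_permutations(K)
    totals <- vapply(perms, function(p) {
      sum(score[cbind(seq_len(K), p)])
    }, numeric(1))
    best <- perms[[which.max(totals)]]
  } else {
    best <- integer(K)
    taken <- logical(K)
    for (i in order(-apply(score, 1L, max))) {
      j <- order(-score[i, ])
      j <- j[!taken[j]][1]
      best[i] <- j
      taken[j] <- TRUE
    }
  }
  list(permutation = best,
       recovery = score[cbind(seq_len(K), best)])
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- all_permutations(K - 1L)
  out <- vector("list", K * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(K)) {
      i <- i + 1L
      out[[i]] <- append(p, K, after = pos - 1L)
    }
  }
  out
}

#' Persist / load a topic model as JSON
#'
#' @param model A `topic_model`.
#' @param path File path.
#' @return `read_topic_model()` returns a `topic_model`.
#' @export
write_topic_model <- function(model, path) {
  stopifnot(inherits(model, "topic_model"))
  payload <- list(K = model$K, vocab = model$vocab,
                  topic_word = unname(apply(model$topic_word, 1L, c,
                                            simplify = FALSE)),
                  doc_topic = unname(apply(model$doc_topic, 1L, c,
                                           simplify = FALSE)),
                  doc_ids = model$doc_ids,
                  hyperparameters = model$hyperparameters,
                  seed = model$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_topic_model
#' @export
read_topic_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_matrix <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  topic_word <- as_matrix(p$topic_word)
  doc_topic <- as_matrix(p$doc_topic)
  colnames(topic_word) <- p$vocab
  rownames(doc_topic) <- p$doc_ids
  structure(list(K = as.integer(p$K), vocab = p$vocab,
                 topic_word = topic_word, doc_topic = doc_topic,
                 doc_ids = p$doc_ids,
                 hyperparameters = p$hyperparameters, seed = p$seed),
            class = "topic_model")
}
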