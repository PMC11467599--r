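#' Train word embeddings on a tokenised corpus
#'
#' Fits skip-gram-with-negative-sampling word vectors (the word2vec/fastText
#' family) on a list of token vectors. Training is single-threaded and
#' fully deterministic under `seed`. Out-of-vocabulary handling in the
#' spirit of character n-gram subword models is available at lookup time:
#' each character n-gram (3-5 characters, with `<`/`>` word boundary
#' markers) is given the mean vector of the vocabulary words containing it,
#' and an unseen token receives the mean of its n-gram vectors — useful for
#' the misspellings endemic to social-media text.
#'
#' @param corpus List of character vectors (token lists), e.g. from
#'   [preprocess_corpus()].
#' @param d Embedding dimension.
#' @param window Maximum context window (dynamic, as in word2vec).
#' @param epochs Training passes over the corpus.
#' @param min_count Minimum token frequency for vocabulary inclusion.
#' @param negative Negative samples per positive pair.
#' @param alpha,min_alpha Initial and final learning rate (linear decay).
#' @param subword Build the character n-gram index for OOV inference.
#' @param seed Integer RNG seed.
#' @return An `embedding_model`: list with `vectors` (vocabulary x d matrix,
#'   rownames are the vocabulary), `counts`, `dim`, `subword`, and training
#'   metadata.
#' @export
train_embeddings <- function(corpus, d = 50, window = 5, epochs = 5,
                             min_count = 1, negative = 5, alpha = 0.05,
                             min_alpha = 1e-4, subword = TRUE, seed = 1) {
  if (length(corpus) == 0L || all(lengths(corpus) == 0L)) {
    stop("corpus is empty: nothing to train on")
  }
  tokens <- unlist(corpus, use.names = FALSE)
  tab <- table(tokens)
  keep <- tab[tab >= min_count]
  # deterministic vocabulary order: frequency-descending, then lexicographic
  vocab <- names(keep)[order(-as.integer(keep), names(keep))]
  if (length(vocab) < 2L) stop("vocabulary has fewer than 2 types")
  counts <- as.numeric(keep[vocab])
  idx <- seq_along(vocab)
  names(idx) <- vocab
  sentences <- lapply(corpus, function(s) {
    ids <- idx[s]
    as.integer(ids[!is.na(ids)] - 1L)
  })
  sentences <- sentences[lengths(sentences) > 1L]
  if (length(sentences) == 0L) stop("no sentence has 2+ in-vocabulary tokens")
  vec <- .sgns_train(sentences, length(vocab), counts, as.integer(d),
                     as.integer(window), as.integer(epochs),
                     as.integer(negative), alpha, min_alpha,
                     as.integer(seed))
  rownames(vec) <- vocab
  model <- list(vectors = vec, counts = stats::setNames(counts, vocab),
                dim = as.integer(d),
                meta = list(window = window, epochs = epochs,
                            min_count = min_count, negative = negative,
                            seed = seed, n_sentences = length(sentences)))
  if (isTRUE(subword)) model$ngrams <- build_ngram_vectors(vec)
  class(model) <- "embedding_model"
  model
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model d=%d, |vocab|=%d, subword=%s>\n",
              x$dim, nrow(x$vectors), !is.null(x$ngrams)))
  invisible(x)
}

token_ngrams <- function(token, n_min = 3L, n_max = 5L) {
  padded <- paste0("<", token, ">")
  L <- nchar(padded)
  out <- character(0)
  for (n in n_min:n_max) {
    if (L < n) break
    starts <- seq_len(L - n + 1L)
    out <- c(out, substring(padded, starts, starts + n - 1L))
  }
  unique(out)
}

build_ngram_vectors <- function(vectors) {
  vocab <- rownames(vectors)
  grams <- lapply(vocab, token_ngrams)
  flat <- unlist(grams, use.names = FALSE)
  word_of <- rep.int(seq_along(vocab), lengths(grams))
  # mean vector of the vocabulary words containing each n-gram
  groups <- split(word_of, flat)
  mat <- t(vapply(groups, function(rows) {
    if (length(rows) == 1L) vectors[rows, ] else colMeans(vectors[rows, , drop = FALSE])
  }, numeric(ncol(vectors))))
  mat
}

#' Look up vectors for tokens, with optional subword inference
#'
#' In-vocabulary tokens return their trained vector. Out-of-vocabulary
#' tokens return the mean of their character n-gram vectors when the model
#' was trained with `subword = TRUE` and at least one n-gram is known;
#' otherwise `NA`.
#'
#' @param model An `embedding_model`.
#' @param tokens Character vector.
#' @return Numeric matrix `length(tokens)` x `d`; rows of `NA` for
#'   unresolvable tokens.
#' @export
embedding_vectors <- function(model, tokens) {
  stopifnot(inherits(model, "embedding_model"))
  out <- matrix(NA_real_, nrow = length(tokens), ncol = model$dim,
                dimnames = list(tokens, NULL))
  hit <- tokens %in% rownames(model$vectors)
  if (any(hit)) out[hit, ] <- model$vectors[tokens[hit], , drop = FALSE]
  if (!is.null(model$ngrams) && any(!hit)) {
    known <- rownames(model$ngrams)
    for (i in which(!hit)) {
      if (!nzchar(tokens[i])) next
      g <- intersect(token_ngrams(tokens[i]), known)
      if (length(g)) {
        out[i, ] <- colMeans(model$ngrams[g, , drop = FALSE])
      }
    }
  }
  out
}

row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m * m))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Cosine similarity between two tokens under a model
#'
#' @param model An `embedding_model`.
#' @param a,b Tokens.
#' @return Cosine similarity in `[-1, 1]`, or `NA` if either token has no
#'   vector.
#' @export
embedding_similarity <- function(model, a, b) {
  v <- embedding_vectors(model, c(a, b))
  if (anyNA(v)) return(NA_real_)
  v <- row_normalize(v)
  sum(v[1, ] * v[2, ])
}

#' Expand a seed lexicon with its embedding-space nearest neighbours
#'
#' Augments a seed term list with the `k` vocabulary terms most similar to
#' the seeds. A candidate's similarity to the seed set is its maximum
#' cosine over the individual seeds (default) or its cosine to the seed
#' centroid. Seeds themselves are excluded from the neighbour list; ties at
#' the cut are broken lexicographically.
#'
#' @param model An `embedding_model`.
#' @param seeds Character vector of seed terms (multiword seeds are split
#'   and their component tokens used for lookup).
#' @param k Number of neighbour terms to add.
#' @param polarity `"relevant"` or `"irrelevant"` — recorded on the result.
#' @param aggregate `"max"` over seeds or `"centroid"`.
#' @return An `expanded_lexicon`: list with `polarity`, `seeds`,
#'   `neighbors`, and `terms` (the union, seeds first).
#' @export
expand_lexicon <- function(model, seeds, k = 50,
                           polarity = c("relevant", "irrelevant"),
                           aggregate = c("max", "centroid")) {
  stopifnot(inherits(model, "embedding_model"), k >= 0)
  polarity <- match.arg(polarity)
  aggregate <- match.arg(aggregate)
  seeds <- unique(tolower(seeds))
  seed_tokens <- unique(unlist(strsplit(seeds, "[[:space:]]+")))
  # anchor expansion on trained vectors; subword-inferred vectors are too
  # noisy to act as nearest-neighbour anchors and are used only when no
  # seed occurs in the vocabulary at all
  in_vocab <- seed_tokens[seed_tokens %in% rownames(model$vectors)]
  if (length(in_vocab)) {
    sv <- model$vectors[in_vocab, , drop = FALSE]
  } else {
    sv <- embedding_vectors(model, seed_tokens)
    sv <- sv[!apply(sv, 1L, anyNA), , drop = FALSE]
    if (nrow(sv) == 0L) stop("no seed term has an embedding vector")
  }
  sv <- row_normalize(sv)
  neighbors <- character(0)
  if (k > 0) {
    vocab <- rownames(model$vectors)
    cand <- setdiff(vocab, c(seeds, seed_tokens))
    if (length(cand)) {
      cv <- row_normalize(model$vectors[cand, , drop = FALSE])
      sims <- cv %*% t(sv)                       # candidates x seeds
      score <- if (aggregate == "max") {
        apply(sims, 1L, max)
      } else {
        cen <- colMeans(sv)
        cen <- cen / sqrt(sum(cen^2))
        drop(cv %*% cen)
      }
      ord <- order(-score, cand)
      neighbors <- cand[ord][seq_len(min(k, length(cand)))]
    }
  }
  structure(list(polarity = polarity, seeds = seeds, neighbors = neighbors,
                 terms = c(seeds, neighbors), aggregate = aggregate, k = k),
            class = "expanded_lexicon")
}

#' @export
print.expanded_lexicon <- function(x, ...) {
  cat(sprintf("<expanded_lexicon %s: %d seeds + %d neighbors>\n",
              x$polarity, length(x$seeds), length(x$neighbors)))
  cat("  neighbors:", paste(utils::head(x$neighbors, 8), collapse = ", "),
      if (length(x$neighbors) > 8) "..." else "", "\n")
  invisible(x)
}

#' Write / read an embedding model in word2vec text format
#'
#' The standard plain-text format: a header line `"<vocab> <dim>"` followed
#' by one `word v1 ... vd` line per vocabulary entry. The n-gram index is
#' rebuilt on read.
#'
#' @param model An `embedding_model`.
#' @param path File path.
#' @param subword Rebuild the subword n-gram index on read.
#' @return `read_embeddings()` returns an `embedding_model`.
#' @export
write_embeddings <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(model$vectors), model$dim), con)
  lines <- paste(rownames(model$vectors),
                 apply(model$vectors, 1L, function(r)
                   paste(formatC(r, format = "g", digits = 17),
                         collapse = " ")))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path, subword = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  vocab <- vapply(parts, `[[`, character(1), 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(vec) <- vocab
  model <- list(vectors = vec, counts = NULL, dim = hdr[2],
                meta = list(source = path))
  if (isTRUE(subword)) model$ngrams <- build_ngram_vectors(vec)
  class(model) <- "embedding_model"
  model
}
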