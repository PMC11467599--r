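# Shared fixtures, all built in code.

# An embedding model with hand-set vectors (no training), for tests whose
# expected values are computed by hand from known geometry.
toy_model <- function(vectors) {
  structure(list(vectors = vectors, counts = NULL, dim = ncol(vectors),
                 meta = list(source = "toy")),
            class = "embedding_model")
}

# 3-d unit geometry: "burn" and "scald" aligned, "water" orthogonal-ish,
# "gym" opposite to "burn".
toy_vectors <- function() {
  m <- rbind(burn = c(1, 0, 0),
             scald = c(0.9, 0.1, 0),
             water = c(0, 1, 0),
             diag = c(1, 1, 0),
             gym = c(-1, 0, 0),
             up = c(0, 0, 1))
  m
}

toy_lexicon <- function(terms, polarity = "relevant") {
  structure(list(polarity = polarity, seeds = terms,
                 neighbors = character(), terms = terms,
                 aggregate = "max", k = 0),
            class = "expanded_lexicon")
}

make_post <- function(id, text, author = "user0001",
                      timestamp = "2019-06-01T12:00:00Z",
                      description = NULL) {
  p <- list(post_id = id, author = author, timestamp = timestamp,
            text = text)
  if (!is.null(description)) p$user_description <- description
  p
}

make_thread <- function(id, texts, platform = "synthforum", title = NULL,
                        authors = NULL, timestamps = NULL) {
  if (is.null(authors)) authors <- rep("user0001", length(texts))
  if (is.null(timestamps)) {
    timestamps <- rep("2019-06-01T12:00:00Z", length(texts))
  }
  posts <- lapply(seq_along(texts), function(i) {
    make_post(sprintf("%s-p%03d", id, i), texts[i], authors[i],
              timestamps[i])
  })
  list(thread_id = id, platform = platform, title = title, posts = posts)
}

# Naive double-loop pairwise-mean similarity: the independent oracle for
# the vectorised scorer.
naive_score <- function(tokens, lex_terms, model) {
  tvec <- embedding_vectors(model, tokens)
  tvec <- tvec[!apply(tvec, 1L, anyNA), , drop = FALSE]
  lterms <- unique(unlist(strsplit(lex_terms, "[[:space:]]+")))
  lvec <- embedding_vectors(model, lterms)
  lvec <- lvec[!apply(lvec, 1L, anyNA), , drop = FALSE]
  if (nrow(tvec) == 0L || nrow(lvec) == 0L) return(NA_real_)
  total <- 0
  for (i in seq_len(nrow(tvec))) {
    for (j in seq_len(nrow(lvec))) {
      a <- tvec[i, ]; b <- lvec[j, ]
      total <- total + sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }
  }
  total / (nrow(tvec) * nrow(lvec))
}

# Small trained model shared across tests that need real embeddings;
# built once per test run.
shared_env <- new.env()
shared_training_model <- function() {
  if (is.null(shared_env$model)) {
    cfg <- synth_config(seed = 101)
    tt <- generate_training_text(cfg, n_sentences = 800)
    shared_env$config <- cfg
    shared_env$model <- train_embeddings(tt, d = 30, epochs = 3,
                                         min_count = 2, seed = 101)
  }
  shared_env$model
}
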