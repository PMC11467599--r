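#' Configuration for the synthetic conversation-corpus generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' multi-post forum threads (or single-tweet "threads") with variable
#' lengths and user counts; posts that use taxonomy terms in the relevant
#' burn-first-aid sense versus ambiguous distractor senses (burning
#' calories, burnout, burning bridges, heartburn); emoji and punctuation
#' noise plus occasional misspellings; calendar-year timestamps spanning
#' 2004-2020 with the yearly intensity profile observed on a large
#' parenting forum; user descriptions carrying parent terms at a
#' configurable rate; and complete gold labels for every generated unit.
#'
#' @param seed Integer master seed; all output is byte-identical under it.
#' @param profile A `platform_profile` for the generated platform.
#' @param n_threads Number of threads (for per-tweet platforms, each
#'   thread is one tweet).
#' @param posts_nb_mu,posts_nb_size Shifted negative-binomial parameters
#'   for posts per thread (`1 + rnbinom(size, mu)`), capped at
#'   `max_posts`.
#' @param max_posts Posts-per-thread cap (default 318, the longest thread
#'   the pipeline is expected to see).
#' @param relevant_fraction Fraction of posts planted as relevant.
#' @param distractor_fraction Of the irrelevant posts, the fraction using
#'   a distractor sense of a burn word (the rest are neutral chatter).
#' @param distractor_mix Weights over the four distractor senses
#'   (calories, burnout, bridges, heartburn).
#' @param years Calendar-year range for timestamps.
#' @param year_weights Sampling weights per year (default: the yearly
#'   post-volume profile of a large parenting forum, rising toward the
#'   present).
#' @param parent_rate Probability a user's description carries a
#'   parent/child term.
#' @param noise_rate Fraction of posts receiving emoji/punctuation noise.
#' @param misspell_rate Fraction of relevant posts receiving one
#'   character-swap misspelling in a filler word (never in a taxonomy
#'   term, so planted labels stay matcher-consistent).
#' @param purpose_probs Thread purpose distribution (seeking, offering,
#'   experience, news); default is forum-like (almost all seeking).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         profile = forum_profile("synthforum"),
                         n_threads = 150,
                         posts_nb_mu = 12.5, posts_nb_size = 0.8,
                         max_posts = 318,
                         relevant_fraction = 0.3,
                         distractor_fraction = 0.4,
                         distractor_mix = c(calories = 0.35, burnout = 0.25,
                                            bridges = 0.2, heartburn = 0.2),
                         years = 2004:2020,
                         year_weights = c(15, 70, 144, 139, 161, 29, 22, 145,
                                          52, 234, 131, 168, 112, 313, 310,
                                          556, 416),
                         parent_rate = 0.06,
                         noise_rate = 0.2,
                         misspell_rate = 0.1,
                         purpose_probs = c(seeking_advice = 0.966,
                                           offering_advice = 0,
                                           experience_sharing = 0.034,
                                           news = 0)) {
  stopifnot(n_threads >= 1,
            relevant_fraction >= 0, relevant_fraction <= 1,
            distractor_fraction >= 0, distractor_fraction <= 1,
            parent_rate >= 0, parent_rate <= 1,
            noise_rate >= 0, noise_rate <= 1,
            misspell_rate >= 0, misspell_rate <= 1,
            length(year_weights) == length(years), all(year_weights >= 0),
            abs(sum(purpose_probs) - 1) < 1e-9)
  structure(list(seed = seed, profile = profile, n_threads = n_threads,
                 posts_nb_mu = posts_nb_mu, posts_nb_size = posts_nb_size,
                 max_posts = max_posts,
                 relevant_fraction = relevant_fraction,
                 distractor_fraction = distractor_fraction,
                 distractor_mix = distractor_mix / sum(distractor_mix),
                 years = years,
                 year_weights = year_weights / sum(year_weights),
                 parent_rate = parent_rate, noise_rate = noise_rate,
                 misspell_rate = misspell_rate,
                 purpose_probs = purpose_probs),
            class = "synth_config")
}

# --- template vocabulary ---------------------------------------------------

synth_vocab <- list(
  hot_object = c("oven", "iron", "kettle", "pan", "stove", "radiator",
                 "hob", "bbq", "hair straighteners"),
  hot_liquid = c("tea", "coffee", "soup", "boiling water", "hot milk"),
  body = c("hand", "arm", "finger", "leg", "shoulder", "face", "foot",
           "wrist", "palm"),
  product = c("aloe", "cream", "gel", "savlon", "sudocrem", "calamine",
              "aftersun", "vaseline", "butter", "honey", "lotion"),
  burn_word = c("burnt", "burned", "burn"),
  scald_word = c("scalded", "scald"),
  sun_word = c("sunburn", "sunburnt", "sunburned"),
  advice_ask = c("any advice please", "what treatment should i use",
                 "what is the best remedy", "how do i treat this",
                 "should i cover it with clingfilm", "does ice help",
                 "any first aid tips"),
  cool_phrase = c("held it under cold running water",
                  "ran it under the cold tap for 20 minutes",
                  "put it under cool water straight away",
                  "used a cold wet cloth as a compress",
                  "pressed frozen peas on it"),
  child_ref = c("my toddler", "my 2 year old", "my little one", "my baby",
                "my 6 month old", "my child"),
  distractor_people = c("friends", "colleagues", "family", "neighbours"),
  gym_word = c("gym", "workout", "exercise", "run", "spin class",
               "treadmill"),
  neutral = c("school run was chaos this morning",
              "anyone watching the telly tonight",
              "looking for a good pasta recipe for dinner",
              "the weather has been awful all week",
              "planning a birthday party for the weekend",
              "the garden needs so much work before summer",
              "homework battles again tonight",
              "booked a holiday to the seaside at last",
              "shopping list keeps getting longer",
              "the park was lovely and quiet today"),
  emoji = c("\U0001F525", "\U0001F631", "\U0001F62D", "❤️",
            "\U0001F44D", "\U0001F3E5"),
  hobbies = c("love baking and long walks", "football fan and tea drinker",
              "gardening and crosswords", "runner and amateur cook",
              "books music and rainy days")
)

pick <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]

relevant_text <- function(kind, with_child) {
  v <- synth_vocab
  child <- if (with_child) paste0(pick(v$child_ref), " ") else ""
  core <- switch(kind,
    contact = sprintf("%s%s %s on the %s", child, pick(v$burn_word),
                      pick(v$body), pick(v$hot_object)),
    scald = sprintf("%s%s %s with %s", child, pick(v$scald_word),
                    pick(v$body), pick(v$hot_liquid)),
    sunburn = sprintf("%sgot %s on %s at the beach", child, pick(v$sun_word),
                      pick(v$body)))
  tail <- if (stats::runif(1) < 0.5) {
    sprintf("%s and put %s on it %s", pick(v$cool_phrase), pick(v$product),
            pick(v$advice_ask))
  } else {
    sprintf("%s is %s a good cure %s", pick(v$cool_phrase), pick(v$product),
            pick(v$advice_ask))
  }
  paste(core, tail)
}

distractor_text <- function(sense) {
  v <- synth_vocab
  switch(sense,
    calories = sprintf("burning calories at the %s again trying to %s off the %s",
                       pick(v$gym_word), pick(c("work", "sweat")),
                       pick(c("cake", "chocolate", "takeaway"))),
    burnout = sprintf("total burnout at work this week the %s and stress are burning all my energy",
                      pick(c("deadlines", "meetings", "emails"))),
    bridges = sprintf("do not burn your bridges with %s over a %s",
                      pick(v$distractor_people),
                      pick(c("silly argument", "job move", "house sale"))),
    heartburn = sprintf("terrible heartburn after that spicy %s the acid is awful",
                        pick(c("curry", "pizza", "chilli"))))
}

swap_chars <- function(word) {
  n <- nchar(word)
  if (n < 4L) return(word)
  i <- sample.int(n - 1L, 1L)
  ch <- strsplit(word, "")[[1]]
  tmp <- ch[i]; ch[i] <- ch[i + 1L]; ch[i + 1L] <- tmp
  paste(ch, collapse = "")
}

taxonomy_tokens <- function() {
  unique(unlist(strsplit(unlist(default_taxonomy()), "[[:space:]]+")))
}

misspell_filler <- function(text, protected) {
  words <- strsplit(text, " ", fixed = TRUE)[[1]]
  cand <- which(!(words %in% protected) & nchar(words) >= 4)
  if (length(cand) == 0L) return(text)
  i <- cand[sample.int(length(cand), 1L)]
  words[i] <- swap_chars(words[i])
  paste(words, collapse = " ")
}

add_noise <- function(text) {
  paste0(text, pick(c("!!!", "...", "!?")),
         " ", paste(pick(synth_vocab$emoji, sample.int(2L, 1L)),
                    collapse = ""))
}

random_timestamp <- function(year) {
  sprintf("%04d-%02d-%02dT%02d:%02d:%02dZ", year,
          sample.int(12L, 1L), sample.int(28L, 1L),
          sample.int(24L, 1L) - 1L, sample.int(60L, 1L) - 1L,
          sample.int(60L, 1L) - 1L)
}

burn_kind_probs <- c(contact = 30, sunburn = 23, scald = 17, chemical = 5,
                     steam = 4, friction = 3, cold = 1, firework = 1,
                     flame = 1, laser = 1, unspecified = 8) / 94
injured_probs <- c(adult = 61, child = 30, pet = 2, unspecified = 1) / 94

#' Generate a synthetic conversation corpus with gold labels
#'
#' Posts are template-composed: relevant posts combine a burn-injury term
#' with first-aid terms (plus a child-reference term on platforms whose
#' queries need one); distractor posts use non-injury senses of burn words
#' alongside exclusion-context vocabulary; neutral posts contain no burn
#' vocabulary. Every post carries a gold relevance label, every thread a
#' purpose label and (when relevant and advice-seeking) a burn-type and
#' injured-party record, and every user a parent-voice flag. Output is
#' fully deterministic under the config seed.
#'
#' @param config A `synth_config`.
#' @return List with `threads` (NDJSON-ready thread records) and `labels`
#'   (list of tibbles: `posts`, `threads`, `users`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_threads < 1) stop("infeasible config: no threads requested")
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  v <- synth_vocab
  per_tweet <- config$profile$analysis_unit != "title_plus_main_post"
  with_child <- config$profile$include_children || per_tweet
  protected <- taxonomy_tokens()

  n_users <- max(8L, as.integer(config$n_threads * 4L))
  user_ids <- sprintf("user%04d", seq_len(n_users))
  user_parent <- stats::runif(n_users) < config$parent_rate
  user_desc <- ifelse(
    user_parent,
    paste(pick(c("proud mum of two", "dad to a toddler",
                 "parent of a little one", "mum of a 3 year old",
                 "raising my baby and loving it"), n_users),
          pick(v$hobbies, n_users)),
    pick(v$hobbies, n_users))

  threads <- vector("list", config$n_threads)
  post_rows <- list()
  thread_rows <- list()

  for (t in seq_len(config$n_threads)) {
    thread_id <- sprintf("%s-%05d", config$profile$platform, t)
    n_posts <- if (per_tweet) 1L else {
      min(config$max_posts,
          1L + stats::rnbinom(1L, size = config$posts_nb_size,
                              mu = config$posts_nb_mu))
    }
    year <- sample(config$years, 1L, prob = config$year_weights)
    purpose <- sample(names(config$purpose_probs), 1L,
                      prob = config$purpose_probs)
    authors_idx <- sample.int(n_users, min(n_posts,
                                           max(1L, ceiling(n_posts * 0.7))),
                              replace = FALSE)
    texts <- character(n_posts)
    kinds <- character(n_posts)
    relevant <- logical(n_posts)
    for (p in seq_len(n_posts)) {
      if (stats::runif(1) < config$relevant_fraction) {
        kind <- sample(c("contact", "scald", "sunburn"), 1L,
                       prob = c(0.45, 0.3, 0.25))
        txt <- relevant_text(kind, with_child)
        if (stats::runif(1) < config$misspell_rate) {
          txt <- misspell_filler(txt, protected)
        }
        texts[p] <- txt; kinds[p] <- kind; relevant[p] <- TRUE
      } else if (stats::runif(1) < config$distractor_fraction) {
        sense <- sample(names(config$distractor_mix), 1L,
                        prob = config$distractor_mix)
        texts[p] <- distractor_text(sense)
        kinds[p] <- paste0("distractor_", sense)
      } else {
        texts[p] <- paste(pick(v$neutral), pick(v$neutral))
        kinds[p] <- "neutral"
      }
      if (stats::runif(1) < config$noise_rate) texts[p] <- add_noise(texts[p])
    }
    stamps <- sort(vapply(seq_len(n_posts), function(i) {
      random_timestamp(year)
    }, character(1)))
    post_authors <- user_ids[authors_idx[
      1L + (seq_len(n_posts) - 1L) %% length(authors_idx)]]
    posts <- lapply(seq_len(n_posts), function(p) {
      aid <- post_authors[p]
      list(post_id = sprintf("%s-p%03d", thread_id, p),
           author = aid,
           timestamp = stamps[p],
           text = texts[p],
           user_description = user_desc[match(aid, user_ids)])
    })
    title <- if (per_tweet) NULL else {
      if (relevant[1]) "help with a burn" else "general chat"
    }
    threads[[t]] <- list(thread_id = thread_id,
                         platform = config$profile$platform,
                         title = title, posts = posts)
    post_rows[[t]] <- tibble::tibble(
      thread_id = thread_id,
      post_id = vapply(posts, `[[`, character(1), "post_id"),
      relevant = relevant, kind = kinds)
    burn_kind <- NA_character_
    injured <- NA_character_
    if (relevant[1] && purpose == "seeking_advice") {
      burn_kind <- if (kinds[1] %in% c("contact", "scald", "sunburn")) {
        kinds[1]
      } else {
        sample(names(burn_kind_probs), 1L, prob = burn_kind_probs)
      }
      injured <- sample(names(injured_probs), 1L, prob = injured_probs)
    }
    thread_rows[[t]] <- tibble::tibble(
      thread_id = thread_id, purpose = purpose,
      first_post_relevant = relevant[1],
      burn_type = burn_kind, injured = injured, year = year)
  }

  labels <- list(posts = do.call(rbind, post_rows),
                 threads = do.call(rbind, thread_rows),
                 users = tibble::tibble(author = user_ids,
                                        parent = user_parent,
                                        description = user_desc))
  list(threads = threads, labels = labels)
}

#' Generate planted-sense training text for embedding training
#'
#' Emits a token corpus whose co-occurrence structure separates the word
#' senses the relevance filter must distinguish: burn-injury terms co-occur
#' with first-aid vocabulary within sentences, while distractor senses
#' co-occur with exclusion-context vocabulary (gym, work, spice). The raw
#' sentences are generated from the same templates as the post corpus and
#' are preprocessed with the package's own normaliser, so training
#' vocabulary and scoring vocabulary coincide.
#'
#' @param config A `synth_config` (uses its seed, distractor mix and
#'   profile).
#' @param n_sentences Number of training sentences (default 3000).
#' @param mix Proportions of relevant / distractor / neutral sentences.
#' @param stopwords Stopword list used in preprocessing.
#' @return List of token character vectors.
#' @export
generate_training_text <- function(config, n_sentences = 3000,
                                   mix = c(relevant = 0.5,
                                           distractor = 0.3,
                                           neutral = 0.2),
                                   stopwords = default_stopwords()) {
  stopifnot(inherits(config, "synth_config"), n_sentences >= 1)
  mix <- mix / sum(mix)
  raw <- with_seed(config$seed + 104729L, {
    vapply(seq_len(n_sentences), function(i) {
      cls <- sample(names(mix), 1L, prob = mix)
      switch(cls,
        relevant = relevant_text(sample(c("contact", "scald", "sunburn"),
                                        1L, prob = c(0.45, 0.3, 0.25)),
                                 with_child = TRUE),
        distractor = distractor_text(
          sample(names(config$distractor_mix), 1L,
                 prob = config$distractor_mix)),
        neutral = paste(pick(synth_vocab$neutral), pick(synth_vocab$neutral)))
    }, character(1))
  })
  preprocess_corpus(raw, stopwords = stopwords)
}

#' Generate documents from a known topic model
#'
#' Standard generative sampling for latent Dirichlet allocation: each
#' document draws a topic mixture from `Dirichlet(alpha)`, then each token
#' draws a topic from the mixture and a word from that topic's
#' distribution. The gold mixtures are returned alongside the documents.
#'
#' @param topic_word K x V matrix of topic-word probabilities (colnames
#'   are the vocabulary; rows must each sum to 1).
#' @param n_docs Number of documents.
#' @param doc_len Tokens per document.
#' @param alpha Symmetric Dirichlet concentration for mixtures.
#' @param seed Integer seed.
#' @return List with `docs` (list of token vectors) and `mixtures`
#'   (`n_docs` x K matrix of gold topic mixtures).
#' @export
generate_topic_corpus <- function(topic_word, n_docs, doc_len,
                                  alpha = 0.3, seed = 1) {
  stopifnot(is.matrix(topic_word), !is.null(colnames(topic_word)),
            all(abs(rowSums(topic_word) - 1) < 1e-8))
  K <- nrow(topic_word)
  vocab <- colnames(topic_word)
  with_seed(seed, {
    mixtures <- matrix(stats::rgamma(n_docs * K, shape = alpha), n_docs, K)
    mixtures <- mixtures / rowSums(mixtures)
    docs <- lapply(seq_len(n_docs), function(d) {
      z <- sample.int(K, doc_len, replace = TRUE, prob = mixtures[d, ])
      vapply(z, function(k) {
        vocab[sample.int(length(vocab), 1L, prob = topic_word[k, ])]
      }, character(1))
    })
    names(docs) <- sprintf("doc%04d", seq_len(n_docs))
    rownames(mixtures) <- names(docs)
    list(docs = docs, mixtures = mixtures)
  })
}

#' K planted topics with disjoint vocabularies
#'
#' Convenience builder for topic-recovery experiments: topic k owns
#' `words_per_topic` words named `t<k>w<j>` and distributes its mass over
#' them with a geometric decay, so top-word lists are unambiguous.
#'
#' @param K Number of topics.
#' @param words_per_topic Vocabulary size per topic.
#' @param decay Geometric decay of within-topic word probabilities.
#' @return K x (K * words_per_topic) topic-word matrix.
#' @export
disjoint_topics <- function(K = 3, words_per_topic = 20, decay = 0.85) {
  vocab <- as.vector(vapply(seq_len(K), function(k) {
    sprintf("t%dw%02d", k, seq_len(words_per_topic))
  }, character(words_per_topic)))
  tw <- matrix(0, K, length(vocab), dimnames = list(NULL, vocab))
  w <- decay^(seq_len(words_per_topic) - 1L)
  w <- w / sum(w)
  for (k in seq_len(K)) {
    tw[k, (k - 1L) * words_per_topic + seq_len(words_per_topic)] <- w
  }
  tw
}
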