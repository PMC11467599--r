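#' Configure an end-to-end pipeline run
#'
#' A single configuration object drives every stage: corpus source
#' (synthetic generator or an NDJSON file), taxonomy and platform profile,
#' embedding-training parameters, lexicon expansion, threshold source
#' (calibrated against gold labels or supplied), topic modeling, and
#' characterization. One master seed derives every stage seed.
#'
#' @param seed Master integer seed.
#' @param synth A `synth_config` for generated corpora (its seed is
#'   overridden by `seed`), or `NULL` when `input_ndjson` is given.
#' @param input_ndjson Path to a thread NDJSON file to ingest instead of
#'   generating (no gold labels; `thresholds` must then be supplied).
#' @param taxonomy A `search_taxonomy`.
#' @param embedding List of [train_embeddings()] parameters
#'   (`d`, `window`, `epochs`, `min_count`, `negative`).
#' @param k_neighbors Lexicon expansion size per polarity.
#' @param neg_strategy Negative-lexicon strategy (see
#'   [relevance_lexicons()]).
#' @param thresholds A `threshold_pair`, or `NULL` to calibrate against
#'   gold labels.
#' @param K Topic count (default 11).
#' @param tau Topic membership threshold.
#' @param topic_iter Gibbs sweeps for the topic model.
#' @param out_dir Optional output directory for stage artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, synth = synth_config(seed = seed),
                            input_ndjson = NULL,
                            taxonomy = default_taxonomy(),
                            embedding = list(d = 50, window = 5, epochs = 5,
                                             min_count = 2, negative = 5),
                            k_neighbors = 50,
                            neg_strategy = "exclusion",
                            thresholds = NULL,
                            K = 11, tau = 0.25, topic_iter = 200,
                            out_dir = NULL) {
  if (!is.null(synth)) synth$seed <- seed
  structure(list(seed = seed, synth = synth, input_ndjson = input_ndjson,
                 taxonomy = taxonomy, embedding = embedding,
                 k_neighbors = k_neighbors, neg_strategy = neg_strategy,
                 thresholds = thresholds, K = K, tau = tau,
                 topic_iter = topic_iter, out_dir = out_dir),
            class = "pipeline_config")
}

log_stage <- function(verbose, stage, ...) {
  if (!verbose) return(invisible())
  entry <- c(list(stage = stage), list(...))
  message(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA))
}

#' Run the full conversation-mining pipeline
#'
#' Executes, in order: corpus generation or ingest, taxonomy query
#' matching with whole-thread selection, embedding training and lexicon
#' expansion, dual-threshold relevance filtering, fixed-K topic modeling
#' with multi-topic assignment, and descriptive characterization. Every
#' stage's input/output counts are recorded in the run manifest, which
#' together with the config reproduces the run exactly. A stage failure
#' aborts with the stage name; the partial manifest accumulated so far is
#' attached to the error condition as `manifest`.
#'
#' @param config A `pipeline_config`.
#' @param verbose Emit one JSON log line per stage.
#' @return A `pipeline_result` list: `manifest`, `threads` (retained),
#'   `model` (embeddings), `lexicons`, `thresholds`, `units` (per-unit
#'   scores), `topics` (`topic_model` or `NULL`), `assignment`, `report`
#'   (`characterization_report` or `NULL`), `labels` (gold labels when
#'   generated).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed, counts = list(),
                   versions = list(
                     convomine = as.character(
                       utils::packageVersion("convomine")),
                     r = paste(R.version$major, R.version$minor, sep = ".")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                 conditionMessage(e)))
      err$manifest <- manifest
      stop(err)
    })
  }

  # -- synth / ingest -------------------------------------------------------
  labels <- NULL
  if (!is.null(config$input_ndjson)) {
    threads <- stage("ingest", read_threads(config$input_ndjson))
    profile <- if (!is.null(config$synth)) config$synth$profile
               else forum_profile("ingested")
  } else {
    gen <- stage("synth", generate_corpus(config$synth))
    threads <- gen$threads
    labels <- gen$labels
    profile <- config$synth$profile
  }
  n_posts <- sum(vapply(threads, function(th) length(th$posts), integer(1)))
  manifest$counts$generated_threads <- length(threads)
  manifest$counts$generated_posts <- n_posts
  manifest$config <- summarize_config(config, profile)
  log_stage(verbose, "synth", threads = length(threads), posts = n_posts)

  # -- query match ----------------------------------------------------------
  queries <- stage("query", compose_queries(config$taxonomy, profile))
  searched <- stage("query", select_threads(threads, queries))
  manifest$counts$searched_threads <- length(searched)
  log_stage(verbose, "query", retained = length(searched))

  if (length(searched) == 0L) {
    manifest$counts[c("filter_units_before", "filter_units_after",
                      "topic_docs", "characterized_threads")] <- 0L
    return(empty_result(manifest, labels))
  }

  # -- embeddings + lexicons ------------------------------------------------
  model <- stage("embed", {
    train_corpus <- if (is.null(config$synth)) {
      preprocess_corpus(unlist(lapply(threads, thread_texts)))
    } else {
      generate_training_text(config$synth)
    }
    emb <- config$embedding
    train_embeddings(train_corpus, d = emb$d, window = emb$window,
                     epochs = emb$epochs, min_count = emb$min_count,
                     negative = emb$negative, seed = config$seed)
  })
  lexicons <- stage("embed",
    relevance_lexicons(model, config$taxonomy, k = config$k_neighbors,
                       strategy = config$neg_strategy))
  log_stage(verbose, "embed", vocab = nrow(model$vectors))

  # -- relevance filter -----------------------------------------------------
  filtered <- stage("filter", {
    units <- analysis_units(searched, profile)
    token_lists <- preprocess_corpus(units$texts)
    scores <- score_units(token_lists, lexicons$pos, lexicons$neg, model)
    thresholds <- config$thresholds
    if (is.null(thresholds)) {
      if (is.null(labels)) {
        stop("no thresholds supplied and no gold labels to calibrate on")
      }
      gold <- unit_gold_labels(searched, units, labels, profile)
      thresholds <- calibrate_thresholds(scores, gold,
                                         platform = profile$platform)
    }
    res <- filter_corpus(searched, profile, lexicons$pos, lexicons$neg,
                         model, thresholds)
    res$thresholds <- thresholds
    res
  })
  manifest$counts$filter_units_before <- filtered$report$n_before
  manifest$counts$filter_units_after <- filtered$report$n_after
  manifest$reduction_pct <- filtered$report$reduction_pct
  log_stage(verbose, "filter", before = filtered$report$n_before,
            after = filtered$report$n_after)

  # -- topics ---------------------------------------------------------------
  topics <- NULL
  assignment <- NULL
  docs <- stage("topics", {
    unit <- analysis_units(filtered$threads, profile)
    d <- preprocess_corpus(unit$texts)
    names(d) <- vapply(seq_along(d), function(i) {
      th <- filtered$threads[[unit$unit_thread[i]]]
      if (is.na(unit$unit_post[i])) th$thread_id
      else th$posts[[unit$unit_post[i]]]$post_id
    }, character(1))
    d[lengths(d) > 0L]
  })
  if (length(docs) >= config$K) {
    topics <- stage("topics",
      fit_topics(docs, K = config$K, n_iter = config$topic_iter,
                 seed = config$seed + 1L))
    assignment <- assign_all_topics(topics, tau = config$tau)
  }
  manifest$counts$topic_docs <- length(docs)
  log_stage(verbose, "topics", docs = length(docs),
            fitted = !is.null(topics))

  # -- characterize ---------------------------------------------------------
  report <- stage("characterize", {
    purpose <- NULL; burn <- NULL
    if (!is.null(labels)) {
      ids <- vapply(filtered$threads, function(th) th$thread_id, character(1))
      lab <- labels$threads[match(ids, labels$threads$thread_id), ]
      purpose <- lab$purpose
      keep <- !is.na(lab$burn_type)
      if (any(keep)) {
        burn <- data.frame(burn_type = lab$burn_type[keep],
                           injured = lab$injured[keep])
      }
    }
    if (length(filtered$threads)) {
      characterize_corpus(filtered$threads, purpose = purpose,
                          burn_records = burn, taxonomy = config$taxonomy)
    }
  })
  manifest$counts$characterized_threads <- length(filtered$threads)
  log_stage(verbose, "characterize", threads = length(filtered$threads))

  result <- structure(list(manifest = manifest, threads = filtered$threads,
                           model = model, lexicons = lexicons,
                           thresholds = filtered$thresholds,
                           units = filtered$units, topics = topics,
                           assignment = assignment, report = report,
                           labels = labels),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

summarize_config <- function(config, profile) {
  list(platform = profile$platform, analysis_unit = profile$analysis_unit,
       embedding = config$embedding, k_neighbors = config$k_neighbors,
       neg_strategy = config$neg_strategy, K = config$K, tau = config$tau,
       topic_iter = config$topic_iter,
       synth = if (!is.null(config$synth)) {
         config$synth[c("seed", "n_threads", "relevant_fraction",
                        "distractor_fraction", "parent_rate", "noise_rate",
                        "misspell_rate")]
       })
}

empty_result <- function(manifest, labels) {
  structure(list(manifest = manifest, threads = list(), model = NULL,
                 lexicons = NULL, thresholds = NULL, units = NULL,
                 topics = NULL, assignment = NULL, report = NULL,
                 labels = labels),
            class = "pipeline_result")
}

unit_gold_labels <- function(threads, units, labels, profile) {
  if (profile$analysis_unit == "title_plus_main_post") {
    ids <- vapply(threads, function(th) th$thread_id, character(1))
    labels$threads$first_post_relevant[match(ids, labels$threads$thread_id)]
  } else {
    pid <- vapply(seq_along(units$texts), function(i) {
      threads[[units$unit_thread[i]]]$posts[[units$unit_post[i]]]$post_id
    }, character(1))
    labels$posts$relevant[match(pid, labels$posts$post_id)]
  }
}

#' @export
print.pipeline_result <- function(x, ...) {
  cts <- x$manifest$counts
  cat("<pipeline_result>\n")
  cat(sprintf("  generated: %d threads / %d posts\n",
              cts$generated_threads, cts$generated_posts))
  cat(sprintf("  searched:  %d threads\n", cts$searched_threads))
  cat(sprintf("  filtered:  %d -> %d units\n",
              cts$filter_units_before %||% 0L,
              cts$filter_units_after %||% 0L))
  cat(sprintf("  topics:    %d docs%s\n", cts$topic_docs %||% 0L,
              if (is.null(x$topics)) " (not fitted)" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the stage artifacts of a pipeline run
#'
#' Writes `manifest.json` (deterministic: no timings, only config, seeds
#' and counts), the retained threads as `filtered.ndjson`, per-unit
#' scores as `units.csv`, the topic model as `topics.json` with a
#' `topic_top_words.csv` sheet and `overlap.csv` matrix, and the
#' characterization tables.
#'
#' @param result A `pipeline_result`.
#' @param config The `pipeline_config` used (for `out_dir`).
#' @return Invisibly, the output directory.
#' @export
write_pipeline_outputs <- function(result, config) {
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  write_threads(result$threads, file.path(dir, "filtered.ndjson"))
  if (!is.null(result$units)) {
    utils::write.csv(result$units, file.path(dir, "units.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$topics)) {
    write_topic_model(result$topics, file.path(dir, "topics.json"))
    nw <- min(20L, length(result$topics$vocab))
    tops <- t(vapply(seq_len(result$topics$K), top_words,
                     character(nw), model = result$topics, n = nw))
    utils::write.csv(data.frame(topic = seq_len(result$topics$K), tops),
                     file.path(dir, "topic_top_words.csv"),
                     row.names = FALSE)
    utils::write.csv(overlap_matrix(result$assignment),
                     file.path(dir, "overlap.csv"), row.names = FALSE)
  }
  if (!is.null(result$report)) {
    write_characterization(result$report, file.path(dir, "characterize"))
  }
  invisible(dir)
}
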