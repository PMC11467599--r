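test_that("pairwise-mean scoring matches hand-computed geometry", {
  m <- toy_model(toy_vectors())
  pos <- toy_lexicon(c("diag", "burn"))
  neg <- toy_lexicon("gym", "irrelevant")
  # cosines: burn.diag = 1/sqrt(2), burn.burn = 1,
  #          water.diag = 1/sqrt(2), water.burn = 0 -> mean (1+sqrt(2))/4
  sc <- score_unit(c("burn", "water"), pos, neg, m)
  expect_equal(sc$pos_mean, (1 + sqrt(2)) / 4, tolerance = 1e-12)
  expect_identical(sc$n_tokens, 2L)
  # self-similarity
  sc1 <- score_unit("burn", toy_lexicon("burn"), neg, m)
  expect_equal(sc1$pos_mean, 1.0, tolerance = 1e-12)
  # no tokens -> undefined
  sc0 <- score_unit(character(), pos, neg, m)
  expect_false(sc0$defined)
  expect_identical(sc0$n_tokens, 0L)
  # unknown tokens are skipped, not scored
  sc2 <- score_unit(c("burn", "unknowntoken"), pos, neg, m)
  expect_identical(sc2$n_tokens, 1L)
})

test_that("vectorised scorer agrees with the naive double loop", {
  m <- shared_training_model()
  vocab <- rownames(m$vectors)
  pos <- toy_lexicon(c("burn", "water", "cream", "treat"))
  neg <- toy_lexicon(c("calorie", "gym", "stress"), "irrelevant")
  set.seed(42)
  units <- lapply(1:100, function(i) {
    sample(vocab, sample(3:12, 1), replace = TRUE)
  })
  sc <- score_units(units, pos, neg, m)
  for (i in seq_along(units)) {
    expect_equal(sc$pos_mean[i], naive_score(units[[i]], pos$terms, m),
                 tolerance = 1e-9)
    expect_equal(sc$neg_mean[i], naive_score(units[[i]], neg$terms, m),
                 tolerance = 1e-9)
  }
})

test_that("scores are invariant to positive rescaling of all vectors", {
  m <- shared_training_model()
  m2 <- m
  m2$vectors <- m$vectors * 7.3
  m2$ngrams <- NULL; m <- m; m$ngrams <- NULL
  pos <- toy_lexicon(c("burn", "water"))
  neg <- toy_lexicon("calorie", "irrelevant")
  u <- list(c("burn", "cream", "cool"), c("gym", "workout"))
  expect_equal(score_units(u, pos, neg, m)$pos_mean,
               score_units(u, pos, neg, m2)$pos_mean, tolerance = 1e-12)
})

test_that("classification applies inclusive dual thresholds", {
  th <- threshold_pair("x", 0.5, 0.0)
  mk <- function(p, n) {
    structure(list(pos_mean = p, neg_mean = n, n_tokens = 3L,
                   defined = TRUE), class = "relevance_score")
  }
  expect_identical(classify(mk(1.0, -1.0), th), "relevant")
  expect_identical(classify(mk(0.5, 0.0), th), "relevant")  # boundaries in
  expect_identical(classify(mk(0.2, 0.9), th), "irrelevant")
  expect_identical(classify(mk(0.6, 0.1), th), "irrelevant")
  undef <- structure(list(pos_mean = NA_real_, neg_mean = NA_real_,
                          n_tokens = 0L, defined = FALSE),
                     class = "relevance_score")
  expect_error(classify(undef, th), "undefined")
})

test_that("calibration recovers perfectly separating thresholds", {
  sc <- tibble::tibble(pos_mean = c(rep(0.9, 10), rep(0.1, 10)),
                       neg_mean = c(rep(-0.5, 10), rep(0.5, 10)),
                       n_tokens = 5L, defined = TRUE)
  gold <- rep(c(TRUE, FALSE), each = 10)
  th <- calibrate_thresholds(sc, gold, resolution = 0.1)
  expect_equal(th$provenance$value, 1.0)
  # deterministic tie-break: smallest theta_pos, then largest theta_neg
  # (the grid minimum 0.1 already yields F1 = 1 because the negative
  # threshold alone excludes the irrelevant half)
  expect_equal(th$theta_pos, 0.1, tolerance = 1e-9)
  expect_equal(th$theta_neg, 0.4, tolerance = 1e-9)
  expect_error(calibrate_thresholds(sc, rep(TRUE, 20)), "both")
})

test_that("calibration objective equals an exhaustive grid oracle", {
  set.seed(8)
  n <- 50
  sc <- tibble::tibble(pos_mean = round(runif(n, -1, 1), 2),
                       neg_mean = round(runif(n, -1, 1), 2),
                       n_tokens = 5L, defined = TRUE)
  gold <- runif(n) < 0.4  # labels independent of scores
  res <- 0.05
  th <- calibrate_thresholds(sc, gold, resolution = res)
  # independent oracle: brute-force loop over the same grid
  gp <- seq(floor(min(sc$pos_mean) / res) * res, max(sc$pos_mean) + res,
            by = res)
  gn <- seq(floor(min(sc$neg_mean) / res) * res, max(sc$neg_mean) + res,
            by = res)
  best <- 0
  for (tp in gp) for (tn in gn) {
    pred <- sc$pos_mean >= tp & sc$neg_mean <= tn
    TP <- sum(pred & gold); FP <- sum(pred & !gold); FN <- sum(!pred & gold)
    f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
    best <- max(best, f1)
  }
  expect_equal(th$provenance$value, best, tolerance = 1e-12)
})

test_that("tightening thresholds never grows the retained set", {
  m <- shared_training_model()
  lex <- relevance_lexicons(m, k = 20)
  cfg <- synth_config(seed = 17, n_threads = 40)
  gen <- generate_corpus(cfg)
  texts <- unlist(lapply(gen$threads, function(th) {
    vapply(th$posts, `[[`, character(1), "text")
  }))
  sc <- score_units(preprocess_corpus(texts), lex$pos, lex$neg, m)
  base <- threshold_pair("x", 0.2, 0.3)
  kept <- function(th) which(classify_relevant(sc, th))
  classify_relevant <- function(s, th) {
    s$defined & s$pos_mean >= th$theta_pos & s$neg_mean <= th$theta_neg
  }
  k0 <- kept(base)
  expect_true(all(kept(threshold_pair("x", 0.3, 0.3)) %in% k0))
  expect_true(all(kept(threshold_pair("x", 0.2, 0.2)) %in% k0))
  expect_true(all(kept(threshold_pair("x", 0.35, 0.15)) %in% k0))
})

test_that("filter reports reproduce percentage reductions from counts", {
  rep1 <- filter_report("forum", "title_plus_main_post", 1972, 594)
  expect_identical(rep1$reduction_pct, 70)
  rep2 <- filter_report("x", "per_tweet", 100, 100)
  expect_identical(rep2$reduction_pct, 0)
  rep3 <- filter_report("reddit", "title_plus_main_post", 1905, 12,
                        decimals = 2)
  expect_identical(rep3$reduction_pct, 99.37)
  expect_error(filter_report("x", "u", 10, 11))
})

test_that("corpus filtering classifies the profile's analysis unit", {
  m <- shared_training_model()
  lex <- relevance_lexicons(m, k = 20)
  th <- threshold_pair("synthforum", 0.3, 0.5)
  rel_text <- "burnt my hand on the oven held it under cold running water any advice"
  irr_text <- "burning calories at the gym trying to work off the cake"
  threads <- list(
    make_thread("a", c(rel_text, irr_text)),
    make_thread("b", c(irr_text, rel_text)))
  # forum: only title+main post decides; thread b's main post is irrelevant
  out <- filter_corpus(threads, forum_profile("synthforum"),
                       lex$pos, lex$neg, m, th)
  expect_identical(vapply(out$threads, `[[`, character(1), "thread_id"), "a")
  expect_identical(out$report$n_before, 2L)
  expect_identical(out$report$n_after, 1L)
  # per-comment: each post is a unit; both threads keep one relevant post
  out2 <- filter_corpus(threads, video_profile("synthforum"),
                        lex$pos, lex$neg, m, th)
  expect_identical(out2$report$n_before, 4L)
  expect_identical(out2$report$n_after, 2L)
  expect_length(out2$threads, 2L)
  expect_length(out2$threads[[1]]$posts, 1L)
  # units with no scorable tokens are classified irrelevant
  threads3 <- list(make_thread("c", "zzqq xxyy"))
  out3 <- filter_corpus(threads3, forum_profile("synthforum"),
                        lex$pos, lex$neg, m, th)
  expect_length(out3$threads, 0L)
})
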