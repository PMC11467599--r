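test_that("pct applies half-up rounding at the requested precision", {
  expect_identical(pct(112, 116, 1), 96.6)
  expect_identical(pct(12, 1905, 2), 0.63)
  expect_identical(pct(0, 94, 1), 0)
  expect_identical(pct(30, 94, 0), 32)
  expect_identical(pct(1, 8, 0), 13)   # .5 rounds up, not to even
  expect_identical(pct(1, 8, 1), 12.5)
  expect_error(pct(1, 0), "positive")
})

test_that("thread statistics match brute-force recomputation", {
  one <- make_thread("a", rep("hi", 5))
  st <- thread_stats(list(one))
  expect_equal(st$mean[1], 5)
  expect_equal(st$min[1], 5)
  expect_equal(st$max[1], 5)
  two <- list(make_thread("a", rep("x", 2)), make_thread("b", rep("x", 4)))
  expect_equal(thread_stats(two)$mean[1], 3)
  # random synthetic corpus against direct recomputation
  gen <- generate_corpus(synth_config(seed = 12, n_threads = 50))
  st <- thread_stats(gen$threads)
  n_posts <- vapply(gen$threads, function(th) length(th$posts), integer(1))
  expect_equal(st$mean[1], mean(n_posts))
  expect_equal(st$sd[1], sd(n_posts))
  expect_equal(st$min[1], min(n_posts))
  expect_equal(st$max[1], max(n_posts))
  n_users <- vapply(gen$threads, function(th) {
    length(unique(vapply(th$posts, `[[`, character(1), "author")))
  }, integer(1))
  expect_equal(st$mean[2], mean(n_users))
})

test_that("anonymous posts count as distinct singleton users", {
  th <- make_thread("a", c("x", "y", "z"),
                    authors = c("u1", NA, NA))
  st <- thread_stats(list(th))
  expect_equal(st$max[2], 3)
  expect_identical(attr(st, "n_anonymous"), 2L)
})

test_that("purpose tabulation conserves counts", {
  labs <- c(rep("seeking_advice", 112), rep("experience_sharing", 4))
  tab <- purpose_table(labs)
  expect_identical(nrow(tab), 4L)
  expect_identical(sum(tab$count), 116L)
  expect_identical(tab$percentage[tab$purpose == "seeking_advice"], 96.6)
  expect_identical(tab$percentage[tab$purpose == "experience_sharing"], 3.4)
  all_off <- purpose_table(rep("offering_advice", 9))
  expect_identical(all_off$percentage[all_off$purpose == "offering_advice"],
                   100)
  expect_identical(sum(all_off$count), 9L)
  expect_error(purpose_table("question"), "unknown")
  # random labels equal a direct tally
  set.seed(3)
  rnd <- sample(c("seeking_advice", "offering_advice",
                  "experience_sharing", "news"), 200, replace = TRUE)
  tab <- purpose_table(rnd)
  for (lv in tab$purpose) {
    expect_identical(tab$count[tab$purpose == lv], sum(rnd == lv))
  }
})

test_that("burn crosstab margins equal their sums", {
  rec <- data.frame(
    burn_type = c(rep("contact", 30), rep("sunburn", 23), rep("scald", 17),
                  rep("chemical", 5), rep("steam", 4), rep("friction", 3),
                  rep("cold", 1), rep("firework", 1), rep("flame", 1),
                  rep("laser", 1), rep("unspecified", 8)),
    injured = "adult")
  rec$injured[1:30] <- c(rep("adult", 16), rep("child", 12), rep("pet", 2))
  tab <- burn_crosstab(rec)
  expect_identical(tab$total[tab$burn_type == "contact"], 30L)
  expect_identical(tab$total_pct[tab$burn_type == "contact"], 32)
  expect_identical(tab$total[tab$burn_type == "total"], 94L)
  # margins: row totals and column totals are sums
  body <- tab[tab$burn_type != "total", ]
  for (col in c("adult", "child", "pet", "unspecified")) {
    expect_identical(sum(body[[col]]),
                     tab[[col]][tab$burn_type == "total"])
  }
  expect_identical(body$adult + body$child + body$pet + body$unspecified,
                   body$total)
  # empty input gives an all-zero table
  empty <- burn_crosstab(data.frame(burn_type = character(),
                                    injured = character()))
  expect_true(all(empty$total == 0L))
})

test_that("yearly counts histogram matches brute force", {
  ts <- c("2019-01-01T00:00:00Z", "2019-12-31T23:59:59Z",
          "2020-06-15T10:00:00Z", "2020-01-01T00:00:00Z")
  tab <- yearly_counts(ts)
  expect_identical(tab$count, c(2L, 2L))
  expect_identical(tab$percentage, c(50, 50))
  one <- yearly_counts(rep("2015-03-03", 7))
  expect_identical(one$percentage, 100)
  # unparseable entries are excluded and counted
  mix <- yearly_counts(c("2019-01-01", "not a date", "2019-05-05"))
  expect_identical(attr(mix, "n_unparseable"), 1L)
  expect_identical(sum(mix$count), 2L)
  # random years: equals table()
  set.seed(9)
  yrs <- sample(2004:2020, 300, replace = TRUE)
  tab <- yearly_counts(sprintf("%d-06-01", yrs))
  for (i in seq_len(nrow(tab))) {
    expect_identical(tab$count[i], sum(yrs == tab$year[i]))
  }
  expect_identical(sum(tab$count), 300L)
})

test_that("term prevalence uses phrase semantics over raw text", {
  units <- c("ran it under cold water", "used aloe vera gel",
             "nothing relevant", "water again \U0001F4A6")
  tab <- term_prevalence(units, c("water", "aloe", "butter", "wet cloth"))
  expect_identical(tab$count[tab$term == "water"], 2L)
  expect_identical(tab$percentage[tab$term == "water"], 50)
  expect_identical(tab$percentage[tab$term == "butter"], 0)
  # multiword terms need a contiguous phrase
  tab2 <- term_prevalence(c("a wet cloth helps", "cloth was wet"),
                          "wet cloth")
  expect_identical(tab2$count, 1L)
  # brute-force scan agreement on a planted fixture
  gen <- generate_corpus(synth_config(seed = 14, n_threads = 30))
  texts <- unlist(lapply(gen$threads, function(th) {
    vapply(th$posts, `[[`, character(1), "text")
  }))
  tab3 <- term_prevalence(texts, c("water", "calories"))
  brute <- sum(grepl("(?<![[:alnum:]])water(?![[:alnum:]])",
                     tolower(texts), perl = TRUE))
  expect_identical(tab3$count[tab3$term == "water"], brute)
})

test_that("top frequent words rank by count and honour exclusions", {
  corp <- list(c("water", "water", "burn"), c("water", "aloe", "burn"))
  tab <- top_frequent_words(corp, n = 2, exclusions = character())
  expect_identical(tab$word, c("water", "burn"))
  expect_identical(tab$count, c(3L, 2L))
  # pronoun-only corpus yields nothing under the default exclusions
  expect_identical(nrow(top_frequent_words(list(c("she", "they", "i")))), 0L)
  # brute-force counter agreement
  gen <- generate_corpus(synth_config(seed = 15, n_threads = 20))
  texts <- unlist(lapply(gen$threads, function(th) {
    vapply(th$posts, `[[`, character(1), "text")
  }))
  corp <- preprocess_corpus(texts)
  tab <- top_frequent_words(corp, n = 10)
  toks <- unlist(corp)
  toks <- toks[!(toks %in% default_stopwords())]
  counts <- sort(table(toks), decreasing = TRUE)
  expect_identical(tab$count[1], as.integer(counts[1]))
  expect_true(all(tab$word %in% names(counts)))
})

test_that("parent-voice detection reproduces the printed rate", {
  # 138 of 2275 descriptions carry a parent term -> 6% at whole-percent
  desc <- c(rep("proud mum of my toddler", 138),
            rep("coffee lover and runner", 2275 - 138))
  pv <- parent_voice(desc, parent_terms = c("toddler", "my kid"))
  expect_identical(pv$count, 138L)
  expect_identical(pv$percentage, 6)
  expect_identical(parent_voice(character())$count, 0L)
  none <- parent_voice(c("no terms here", NA))
  expect_identical(none$count, 0L)
  expect_identical(none$percentage, 0)
})

test_that("all emitted tables stay count-consistent on random fixtures", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    labs <- sample(c("seeking_advice", "offering_advice",
                     "experience_sharing", "news"), n, replace = TRUE)
    tab <- purpose_table(labs)
    expect_identical(sum(tab$count), n)
    expect_equal(tab$percentage, pct(tab$count, n, 1))
    rec <- data.frame(
      burn_type = sample(c("contact", "sunburn", "scald", "unspecified"),
                         n, replace = TRUE),
      injured = sample(c("adult", "child", "pet", "unspecified"),
                       n, replace = TRUE))
    ct <- burn_crosstab(rec)
    body <- ct[ct$burn_type != "total", ]
    expect_identical(sum(body$total), ct$total[ct$burn_type == "total"])
    expect_identical(body$adult + body$child + body$pet + body$unspecified,
                     body$total)
    expect_equal(body$total_pct, pct(body$total, n, 0))
  }
})

test_that("the combined report bundles consistent tables", {
  gen <- generate_corpus(synth_config(seed = 19, n_threads = 40))
  rep <- characterize_corpus(gen$threads,
                             purpose = gen$labels$threads$purpose)
  expect_s3_class(rep, "characterization_report")
  expect_identical(sum(rep$purpose$count), 40L)
  expect_identical(sum(rep$yearly$count), rep$n_posts)
  expect_lte(nrow(rep$top_words), 50L)
  d <- withr::local_tempdir()
  write_characterization(rep, d)
  expect_true(file.exists(file.path(d, "purpose.csv")))
  expect_true(file.exists(file.path(d, "report.json")))
  back <- read.csv(file.path(d, "purpose.csv"))
  expect_identical(as.integer(back$count), rep$purpose$count)
})
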