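test_that("packaged taxonomy has the documented category sizes", {
  tax <- default_taxonomy()
  expect_s3_class(tax, "search_taxonomy")
  expect_identical(lengths(tax)[["burn_injury"]], 9L)
  expect_identical(lengths(tax)[["fa_general"]], 10L)
  expect_identical(lengths(tax)[["fa_specific"]], 25L)  # "lotion" stored once
  expect_identical(lengths(tax)[["fa_food"]], 11L)
  expect_identical(lengths(tax)[["children"]], 16L)
  expect_identical(lengths(tax)[["exclusion"]], 9L)
  for (cat in tax) {
    expect_false(anyDuplicated(cat) > 0)
    expect_identical(cat, tolower(cat))
  }
})

test_that("taxonomy constructor rejects invalid categories", {
  tax <- unclass(default_taxonomy())
  expect_error(search_taxonomy(tax[-1]), "six categories")
  bad <- tax; bad$exclusion <- c(bad$exclusion, "out")
  expect_error(search_taxonomy(bad), "duplicate")
  bad <- tax; bad$children <- c(bad$children, "Toddler")
  expect_error(search_taxonomy(bad), "lowercase")
})

test_that("query composition splits the taxonomy into three queries", {
  tax <- default_taxonomy()
  qf <- compose_queries(tax, forum_profile())
  expect_length(qf, 3L)
  fa <- vapply(qf, function(q) names(q$required_groups)[2], character(1))
  expect_setequal(fa, c("fa_general", "fa_specific", "fa_food"))
  # parent-specific forums: no children group, no exclusions
  for (q in qf) {
    expect_identical(names(q$required_groups)[1], "burn_injury")
    expect_false("children" %in% names(q$required_groups))
    expect_length(q$excluded_terms, 0L)
  }
  qm <- compose_queries(tax, microblog_profile())
  for (q in qm) {
    expect_true("children" %in% names(q$required_groups))
    expect_identical(q$excluded_terms, tax$exclusion)
    expect_lte(nchar(render_query(q)), 1024L)
  }
})

test_that("an infeasible character budget is an explicit error", {
  expect_error(
    compose_queries(default_taxonomy(),
                    microblog_profile(char_budget = 40)),
    "budget")
})

test_that("query rendering then parsing is the identity on term groups", {
  tax <- default_taxonomy()
  for (q in compose_queries(tax, microblog_profile())) {
    p <- parse_query(render_query(q, dialect = "boolean"))
    expect_identical(p$required_groups, unname(q$required_groups))
    expect_identical(p$excluded_terms, q$excluded_terms)
  }
})

test_that("text matching follows word-boundary phrase semantics", {
  tax <- default_taxonomy()
  q_gen <- compose_queries(tax, forum_profile())[[1]]  # burn + fa_general
  expect_true(match_text("Burnt my hand on the iron, any remedy?", q_gen))
  expect_false(match_text("", q_gen))
  expect_false(match_text(NA_character_, q_gen))
  # burn term without any first-aid term fails the conjunction
  expect_false(match_text("burnt my toast again", q_gen))
  # terms never match inside longer words
  expect_false(match_text("heartburn ruined the remedy", q_gen))
  expect_true(match_text("my burn needs a remedy", q_gen))
  # multiword phrase must be contiguous
  q_spec <- compose_queries(tax, forum_profile())[[2]]
  expect_true(match_text("burnt myself, used frozen peas", q_spec))
  expect_false(match_text("burnt myself, the peas were not frozen solid",
                          q_spec))
  # "yo" matches only as a standalone token
  qm <- compose_queries(tax, microblog_profile())[[1]]
  expect_true(match_text("my 3 yo burnt a hand, advice?", qm))
  expect_false(match_text("you burnt a hand, advice?", qm))
})

test_that("exclusion terms veto otherwise matching text", {
  tax <- default_taxonomy()
  qm <- compose_queries(tax, microblog_profile())[[1]]
  base <- "my toddler burnt a hand, advice please"
  expect_true(match_text(base, qm))
  expect_false(match_text(paste(base, "while burning calories"), qm))
  expect_false(match_text("burning calories down at the gym", qm))
})

test_that("matching is monotone in term additions", {
  tax <- default_taxonomy()
  cfg <- synth_config(seed = 21, n_threads = 40)
  gen <- generate_corpus(cfg)
  texts <- unlist(lapply(gen$threads, function(th) {
    vapply(th$posts, `[[`, character(1), "text")
  }))
  q <- compose_queries(tax, forum_profile())[[1]]
  matched <- vapply(texts, match_text, logical(1), query = q)
  # adding a term to a required group can only add matches
  q_more <- q
  q_more$required_groups$fa_general <-
    c(q_more$required_groups$fa_general, "tip")
  matched_more <- vapply(texts, match_text, logical(1), query = q_more)
  expect_true(all(matched_more >= matched))
  # adding an exclusion term can only remove matches
  q_excl <- q
  q_excl$excluded_terms <- c(q_excl$excluded_terms, "hand")
  matched_excl <- vapply(texts, match_text, logical(1), query = q_excl)
  expect_true(all(matched_excl <= matched))
})

test_that("whole threads are retained and merged without duplicates", {
  tax <- default_taxonomy()
  queries <- compose_queries(tax, forum_profile())
  hit <- "scalded my arm with tea, ran it under the cold tap"
  th1 <- make_thread("t1", c("nothing here", "still nothing", "quiet",
                             "more chat", hit))
  th2 <- make_thread("t2", c("no burns discussed", "none"))
  # t3 matches both the general and food query
  th3 <- make_thread("t3", "burnt finger, tried butter then a remedy")
  out <- select_threads(list(th1, th2, th3), queries)
  ids <- vapply(out, `[[`, character(1), "thread_id")
  expect_identical(ids, c("t1", "t3"))
  expect_length(out[[1]]$posts, 5L)  # whole thread, not just matching post
  expect_identical(select_threads(list(th2), queries), list())
  expect_error(select_threads(list(th1, th1), queries), "unique")
})

test_that("selected threads are always a duplicate-free subset", {
  cfg <- synth_config(seed = 33, n_threads = 30)
  gen <- generate_corpus(cfg)
  queries <- compose_queries(default_taxonomy(), forum_profile())
  # duplicated query multiset must not duplicate output
  out <- select_threads(gen$threads, c(queries, queries))
  ids <- vapply(out, `[[`, character(1), "thread_id")
  all_ids <- vapply(gen$threads, `[[`, character(1), "thread_id")
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(ids %in% all_ids))
})
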