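test_that("rule matching is token-level with phrase support", {
  vac <- rule_set("vaccines", c("pfizer", "astrazeneca"))
  expect_true(rule_matches(vac, c("la", "vacuna", "pfizer")))
  expect_false(rule_matches(vac, character(0)))
  # token-level, not substring
  expect_false(rule_matches(rule_set("c", "covid"), "covidiota"))
  # contiguous phrase
  ph <- rule_set("mask", "cubre bocas")
  expect_true(rule_matches(ph, c("el", "cubre", "bocas", "ya")))
  expect_false(rule_matches(ph, c("cubre", "la", "bocas")))
  expect_error(rule_set("empty", character(0)), "keyword")
})

test_that("classify_topics returns all matching topics", {
  topics <- default_topic_rules()
  t1 <- classify_topics(c("pfizer", "y", "desempleo"), topics)
  expect_setequal(t1, c("vaccines", "employment"))
  expect_identical(classify_topics(c("nada", "interesante"), topics),
                   character(0))
  expect_identical(classify_topics(tokenize(normalize_term("corrupción")),
                                   topics), "government")
})

test_that("filter_stream applies the three stages in order", {
  raws <- raw_tweets(
    c("la vacuna covid llegó con pfizer",   # retained: context+topic+country
      "la vacuna pfizer llegó",             # no context keyword
      "el covid sigue aqui",                # context but no topic
      "covid y pfizer en otro pais"),       # wrong country
    days = "2020-03-01",
    countries = c("ES", "ES", "ES", "US")
  )
  fl <- filter_stream(raws, default_context_rules(), default_topic_rules(),
                      countries = c("ES", "MX"))
  expect_identical(nrow(fl$tweets), 1L)
  expect_identical(fl$tweets$id, "t001")
  expect_identical(fl$tweets$topics[[1]], "vaccines")
  expect_identical(fl$counts$counts["ES", "vaccines"], 1)
  expect_identical(fl$counts$grand_total, 1)
})

test_that("tweets without country codes are dropped at the country stage", {
  raws <- raw_tweets("covid y pfizer", days = "2020-03-01", countries = NA)
  fl <- filter_stream(raws, default_context_rules(), default_topic_rules(),
                      countries = "ES")
  expect_identical(nrow(fl$tweets), 0L)
  expect_identical(fl$counts$grand_total, 0)
})

test_that("multi-topic tweets are counted once per topic", {
  raws <- raw_tweets("covid pfizer desempleo", days = "2020-03-01")
  fl <- filter_stream(raws, default_context_rules(), default_topic_rules(),
                      countries = "ES")
  expect_identical(nrow(fl$tweets), 1L)
  expect_setequal(fl$tweets$topics[[1]], c("vaccines", "employment"))
  expect_identical(fl$counts$row_totals[["ES"]], 2)
})

test_that("filtering is stable under input reordering and monotone in keywords", {
  set.seed(9)
  texts <- replicate(80, paste(
    sample(c("covid", "pfizer", "hola", "mundo", "estres", "nada"),
           5, replace = TRUE), collapse = " "))
  raws <- raw_tweets(texts, days = "2020-03-01",
                     countries = sample(c("ES", "MX", "US"), 80, replace = TRUE))
  ctx <- default_context_rules()
  tps <- default_topic_rules()
  fl1 <- filter_stream(raws, ctx, tps, countries = c("ES", "MX"))
  perm <- sample(nrow(raws))
  fl2 <- filter_stream(raws[perm], ctx, tps, countries = c("ES", "MX"))
  expect_setequal(fl1$tweets$id, fl2$tweets$id)
  expect_identical(fl1$counts$grand_total, fl2$counts$grand_total)

  # adding a keyword never removes a retained tweet
  tps2 <- c(tps, list(rule_set("extra", "mundo")))
  fl3 <- filter_stream(raws, ctx, tps2, countries = c("ES", "MX"))
  expect_true(all(fl1$tweets$id %in% fl3$tweets$id))
})

test_that("report_counts computes additive totals and rejects negatives", {
  chile <- c(709, 584, 2407, 4131, 6928)
  m <- matrix(chile, 1, dimnames = list("Chile", paste0("t", 1:5)))
  rc <- report_counts(m)
  expect_identical(rc$row_totals[["Chile"]], 14759)
  zero <- report_counts(matrix(0, 2, 3,
                               dimnames = list(c("a", "b"), c("x", "y", "z"))))
  expect_identical(zero$grand_total, 0)
  expect_error(report_counts(matrix(c(1, -1), 1)), "non-negative")

  # additivity on random grids
  set.seed(21)
  for (i in 1:20) {
    g <- matrix(rpois(12, 50), 3, 4,
                dimnames = list(paste0("c", 1:3), paste0("t", 1:4)))
    rc <- report_counts(g)
    expect_equal(rc$row_totals, rowSums(g))
    expect_equal(rc$grand_total, sum(rc$row_totals))
    expect_equal(sum(rc$col_totals), rc$grand_total)
  }
})

test_that("the reference corpus grid reproduces its published totals", {
  rc <- report_counts(covid_corpus_counts())
  expect_identical(unname(rc$row_totals), c(14759, 32713, 6916, 51109))
  expect_identical(rc$grand_total, 105497)
})
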