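test_that("score_tweet averages matched polarities per occurrence", {
  lex <- lexicon(c("a", "b", "c"), c(0.5, -0.1, 0.2))
  expect_equal(score_tweet(c("a", "b", "c"), lex)$score, 0.2)
  expect_true(is.na(score_tweet(c("x", "y"), lex)$score))
  expect_equal(score_tweet("a", lexicon("a", 0.6))$score, 0.6)
  # repeats count per occurrence
  expect_equal(score_tweet(c("a", "a", "b"), lex)$score,
               mean(c(0.5, 0.5, -0.1)))
  # defined score lies within [min, max] of matched polarities
  s <- score_tweet(c("a", "b"), lex)
  expect_gte(s$score, -0.1)
  expect_lte(s$score, 0.5)
})

test_that("daily_update follows the smoothing rule and its limits", {
  lex <- lexicon(c("w", "aux"), c(-0.3, 0.9))
  batch <- lemma_batch(list(c("w", "aux")), "2020-03-01")
  # alpha = 1: full replacement by the daily mean, here mean(-0.3, 0.9) = 0.3
  res <- daily_update(batch, lex, engine_config(alpha = 1))
  expect_equal(res$lexicon[res$lexicon$lemma == "w"]$polarity, 0.3)
  expect_identical(res$records[res$records$lemma == "w"]$daily_count, 1L)

  # alpha = 0.25, prior 0, evidence 1
  lex2 <- lexicon(c("w", "uno"), c(0, 1))
  batch2 <- lemma_batch(list(c("w", "uno", "uno", "uno")), "2020-03-01")
  # score = mean(0, 1, 1, 1) = 0.75; m_w = 0.75
  res2 <- daily_update(batch2, lex2, engine_config(alpha = 0.25))
  expect_equal(res2$lexicon[res2$lexicon$lemma == "w"]$polarity,
               0.75 * 0 + 0.25 * 0.75)

  # word absent on the day: unchanged, no record
  res3 <- daily_update(lemma_batch(list("uno"), "2020-03-01"), lex2,
                       engine_config())
  expect_equal(res3$lexicon[res3$lexicon$lemma == "w"]$polarity, 0)
  expect_false("w" %in% res3$records$lemma)

  # mixed-day batch is an error
  mixed <- rbind(lemma_batch(list("w"), "2020-03-01"),
                 lemma_batch(list("w"), "2020-03-02"))
  expect_error(daily_update(mixed, lex, engine_config()), "one day")
})

test_that("learn_new_words inserts qualifying unknown lemmas", {
  lex <- lexicon(c("p2", "p4", "p6"), c(0.2, 0.4, 0.6))
  batch <- lemma_batch(list(c("nueva", "p2"), c("nueva", "p4"),
                            c("nueva", "p6"), c("soloindefinida", "zz")),
                       "2020-03-05")
  cfg <- engine_config(min_learn_occurrences = 2L)
  out <- learn_new_words(batch, lex, cfg)
  got <- out[out$lemma == "nueva"]
  expect_identical(got$origin, "learned")
  expect_identical(got$created_on, as.Date("2020-03-05"))
  expect_equal(got$polarity, mean(c(0.2, 0.4, 0.6)))
  # lemma appearing only in undefined-score tweets is not learned
  expect_false("soloindefinida" %in% out$lemma)
  # threshold respected
  out3 <- learn_new_words(batch, lex, engine_config(min_learn_occurrences = 4L))
  expect_false("nueva" %in% out3$lemma)
  # switch off
  expect_identical(
    nrow(learn_new_words(batch, lex,
                         engine_config(learn_enabled = FALSE))),
    nrow(lex)
  )
})

test_that("run_stream matches the hand-traced 2-day fixture", {
  # seed: bueno 0.8, malo -0.6, covid -0.2; alpha = 0.5, learn threshold 2
  lex <- lexicon(c("bueno", "malo", "covid"), c(0.8, -0.6, -0.2))
  cfg <- engine_config(alpha = 0.5, min_learn_occurrences = 2L)
  d1 <- lemma_batch(list(c("bueno", "vacuna"),
                         c("malo", "covid", "vacuna")), "2020-03-01",
                    ids = c("a1", "a2"))
  d2 <- lemma_batch(list(c("vacuna", "bueno"), "vacuna"), "2020-03-02",
                    ids = c("a3", "a4"))
  res <- run_stream(rbind(d1, d2), lex, cfg)
  a <- data.table::as.data.table(res$archive)

  # day 1: scores 0.8 and mean(-0.6, -0.2) = -0.4
  expect_equal(a[lemma == "bueno" & day == as.Date("2020-03-01")]$polarity_after, 0.8)
  expect_equal(a[lemma == "malo"]$polarity_after, 0.5 * -0.6 + 0.5 * -0.4)
  expect_equal(a[lemma == "covid"]$polarity_after, 0.5 * -0.2 + 0.5 * -0.4)
  # vacuna learned on day 1 at mean(0.8, -0.4) = 0.2, no day-1 record
  expect_false("vacuna" %in% a[day == as.Date("2020-03-01")]$lemma)
  lx <- res$lexicon
  expect_identical(lx[lx$lemma == "vacuna"]$origin, "learned")

  # day 2: scores mean(0.2, 0.8) = 0.5 and 0.2; m_vacuna = 0.35
  v2 <- a[lemma == "vacuna" & day == as.Date("2020-03-02")]
  expect_equal(v2$daily_mean, 0.35)
  expect_equal(v2$polarity_after, 0.5 * 0.2 + 0.5 * 0.35)
  expect_identical(v2$daily_count, 2L)
  b2 <- a[lemma == "bueno" & day == as.Date("2020-03-02")]
  expect_equal(b2$polarity_after, 0.5 * 0.8 + 0.5 * 0.5)
  expect_equal(lx[lx$lemma == "vacuna"]$polarity, v2$polarity_after)
  # frequencies accumulate defined-score containment counts
  expect_identical(lx[lx$lemma == "bueno"]$total_frequency, 2L)
  expect_identical(lx[lx$lemma == "vacuna"]$total_frequency, 4L)
})

test_that("run_stream on an empty stream returns an empty archive", {
  lex <- tiny_lexicon()
  res <- run_stream(lemma_batch(list(), as.Date(character(0))), lex,
                    engine_config())
  expect_identical(nrow(res$archive), 0L)
  expect_identical(res$lexicon$polarity, lex$polarity)
})

test_that("identical positive evidence drives monotone convergence", {
  lex <- lexicon(c("w", "top"), c(-0.8, 1))
  days <- as.Date("2020-03-01") + 0:9
  stream <- data.table::rbindlist(lapply(seq_along(days), function(i)
    lemma_batch(list(c("w", "top", "top", "top")), days[i],
                ids = sprintf("d%02d", i))))
  res <- run_stream(stream, lex, engine_config(alpha = 0.3,
                                               learn_enabled = FALSE))
  ser <- get_series(res$archive, "w")
  expect_identical(nrow(ser), 10L)
  expect_true(all(diff(ser$polarity_after) > 0))
  expect_true(all(abs(ser$polarity_after) <= 1))
})

test_that("update_polarity satisfies boundedness, pull and the closed form", {
  set.seed(13)
  for (i in 1:50) {
    alpha <- runif(1, 0.01, 1)
    s0 <- runif(1, -1, 1)
    m <- runif(1, -1, 1)
    D <- sample(1:100, 1)
    s <- s0
    for (d in seq_len(D)) s <- update_polarity(s, m, alpha)
    expect_equal(s, m + (1 - alpha)^D * (s0 - m), tolerance = 1e-12)
    expect_true(abs(s) <= 1)
  }
})
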