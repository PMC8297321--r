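test_that("fixture lexicon is the uniform polarity grid", {
  lex <- generate_fixture_lexicon(21)
  expect_identical(nrow(lex), 21L)
  expect_equal(lex[order(lex$polarity)]$polarity, seq(-1, 1, by = 0.1))
  expect_true(all(abs(lex$polarity) <= 1))
  expect_identical(generate_fixture_lexicon(21)$lemma,
                   generate_fixture_lexicon(21)$lemma)
  expect_error(generate_fixture_lexicon(20), "at least 21")
  # lemmas survive the default lemmatizer unchanged
  expect_identical(default_lemmatizer(lex$lemma), lex$lemma)
})

test_that("trajectory_value realises the three shapes", {
  lin <- trajectory_spec("ww", "linear", -0.6, 0.6)
  expect_equal(trajectory_value(lin, c(1, 60), 60), c(-0.6, 0.6))
  expect_equal(trajectory_value(lin, 30.5, 60), 0)
  cst <- trajectory_spec("ww", "constant", 0.5)
  expect_equal(trajectory_value(cst, 1:5, 60), rep(0.5, 5))
  stp <- trajectory_spec("ww", "step", 0.4, -0.4, step_day = 30)
  expect_equal(trajectory_value(stp, c(29, 30), 60), c(0.4, -0.4))
  expect_error(trajectory_spec("ww", "step", 0, 1), "step_day")
  expect_error(trajectory_spec("ww", "constant", 1.5), "\\[-1, 1\\]")
})

test_that("a noiseless planted tweet scores on the planted value", {
  cfg <- synth_config(
    seed = 1L, n_days = 1L, countries = "ES", noise_sd = 0,
    trajectories = list(trajectory_spec("reunion", "constant", 0.5,
                                        tweets_per_day = 1L)),
    word_topics = c(reunion = "employment"),
    background_tweets_per_day = 0L
  )
  lex <- scenario_lexicon(cfg)
  gen <- generate_stream(cfg, lex)
  expect_identical(nrow(gen$tweets), 1L)
  proc <- process_stream(gen$tweets, stopwords = scenario_stopwords(cfg))
  sc <- score_tweet(proc$lemmas[[1]], lex)
  grid_res <- 2 / (cfg$filler_lexicon_size - 1)
  expect_lte(abs(sc$score - 0.5), grid_res)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_synth_config()
  a <- generate_stream(cfg)
  b <- generate_stream(cfg)
  expect_identical(a$tweets, b$tweets)
  expect_identical(a$truth, b$truth)
  c <- generate_stream(small_synth_config(seed = 8L))
  expect_false(identical(a$tweets$text, c$tweets$text))
})

test_that("zero days yields an empty stream", {
  cfg <- synth_config(n_days = 0L, background_tweets_per_day = 0L)
  gen <- generate_stream(cfg)
  expect_identical(nrow(gen$tweets), 0L)
  expect_identical(nrow(gen$truth), 0L)
})

test_that("trajectory tweets pass the filter fully; background tweets never do", {
  cfg <- small_synth_config()
  gen <- generate_stream(cfg)
  rules <- scenario_rules(cfg)
  fl <- filter_stream(gen$tweets, rules$context, rules$topics, cfg$countries,
                      stopwords = scenario_stopwords(cfg))
  n_traj <- sum(vapply(cfg$trajectories, function(tr)
    tr$tweets_per_day * cfg$n_days * length(cfg$countries), 0L))
  expect_identical(nrow(fl$tweets), n_traj)
  # generator labels: trajectory ids come first, background ids after
  traj_ids <- gen$tweets$id[seq_len(n_traj)]
  expect_setequal(fl$tweets$id, traj_ids)
})

test_that("recovery_metrics handles identity, constants and short series", {
  days <- as.Date("2020-03-01") + 0:9
  truth <- data.frame(lemma = "w", country = "ES", day = days,
                      mu = seq(-0.5, 0.4, by = 0.1))
  arch <- sentiment_archive(data.frame(
    country = "ES", lemma = "w", day = days, polarity_after = truth$mu,
    daily_mean = truth$mu, daily_count = 1L
  ))
  m <- recovery_metrics(truth, arch)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$rmse, 0)
  expect_false(m$flagged)

  # constant planted series: r undefined, flagged, rmse still reported
  truth2 <- transform(truth, mu = 0.2)
  m2 <- recovery_metrics(truth2, arch)
  expect_true(m2$flagged)
  expect_true(is.na(m2$pearson_r))
  expect_equal(m2$rmse, sqrt(mean((0.2 - truth$mu)^2)))

  # fewer than 3 common days is flagged
  m3 <- recovery_metrics(truth[1:2, ], arch)
  expect_true(m3$flagged)
  expect_identical(m3$n_common, 2L)
})

test_that("the small scenario recovers its planted trajectories per country", {
  res <- run_recovery_scenario(small_synth_config())
  m <- res$metrics
  expect_identical(nrow(m), 4L)  # 2 words x 2 countries
  lin <- m[m$lemma == "vacuna"]
  expect_true(all(lin$pearson_r > 0.9))
  cst <- m[m$lemma == "reunion"]
  expect_true(all(cst$flagged))        # zero planted variance
  expect_true(all(cst$rmse < 0.15))
  # only the trajectory words are learned
  learned <- res$lexicon[res$lexicon$origin == "learned"]$lemma
  expect_setequal(learned, c("vacuna", "reunion"))
})
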