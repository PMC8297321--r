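test_that("cooccurrence matches brute-force pair counting", {
  # perfect co-occurrence and disjoint words
  tw <- list(c("a", "b"), c("a", "b"), c("a", "b"), c("a", "b"),
             c("a", "b"), "c")
  M <- cooccurrence(tw, c("a", "b", "c"))
  expect_identical(unname(M$counts["a", "b"]), 5L)
  expect_identical(unname(diag(M$counts)), c(5L, 5L, 1L))
  expect_identical(unname(M$counts["a", "c"]), 0L)
  expect_identical(M$doc_count, 6L)

  # random fixture vs O(n V^2) oracle
  set.seed(5)
  vocab <- letters[1:6]
  tweets <- replicate(10, sample(vocab, sample(1:4, 1)), simplify = FALSE)
  M2 <- cooccurrence(tweets, vocab)
  for (i in seq_along(vocab)) {
    for (j in seq_along(vocab)) {
      brute <- sum(vapply(tweets, function(t)
        vocab[i] %in% t && vocab[j] %in% t, NA))
      expect_identical(unname(M2$counts[i, j]), as.integer(brute))
    }
  }
  # symmetry and bound by diagonals
  expect_identical(M2$counts, t(M2$counts))
  d <- diag(M2$counts)
  expect_true(all(M2$counts <= pmin(outer(d, d, pmin), Inf)))
  # multiplicity within a tweet does not inflate counts
  expect_identical(unname(cooccurrence(list(c("a", "a")), "a")$counts[1, 1]), 1L)
})

test_that("ppmi_similarity matches a hand-computed 3-word fixture", {
  tw <- list(c("a", "b"), c("a", "b"), "a", "c")
  S <- ppmi_similarity(cooccurrence(tw, c("a", "b", "c")))
  # independent arithmetic: N=4, d=(3,2,1), C_ab=2
  # ppmi rows: a = [log(4/3), log(4/3), 0]; b = [log(4/3), log(2), 0];
  #            c = [0, 0, log(4)]
  ra <- c(log(4 / 3), log(4 / 3), 0)
  rb <- c(log(4 / 3), log(2), 0)
  cos_ab <- sum(ra * rb) / sqrt(sum(ra^2) * sum(rb^2))
  expect_equal(unname(S["a", "b"]), cos_ab, tolerance = 1e-12)
  expect_equal(unname(S["a", "c"]), 0)
  expect_equal(unname(diag(S)), c(1, 1, 1))
  expect_identical(S, t(S))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("identical and orthogonal profiles hit the similarity extremes", {
  # two words always together: identical PPMI rows -> similarity 1
  tw <- list(c("a", "b"), c("a", "b"), "c")
  S <- ppmi_similarity(cooccurrence(tw, c("a", "b", "c")))
  expect_equal(unname(S["a", "b"]), 1)
  expect_equal(unname(S["a", "c"]), 0)
  # zero-occurrence word: similarity 0 to all others
  S2 <- ppmi_similarity(cooccurrence(tw, c("a", "b", "fantasma")))
  expect_equal(unname(S2["a", "fantasma"]), 0)
})

test_that("cloud_layout is a faithful classical MDS with fixed conventions", {
  # coincident points for perfect similarity
  S <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  xy <- cloud_layout(S)
  expect_equal(unname(xy[1, ]), unname(xy[2, ]), tolerance = 1e-12)

  # similar pair closer than dissimilar pair
  S3 <- diag(3)
  S3[1, 2] <- S3[2, 1] <- 1
  rownames(S3) <- colnames(S3) <- c("a", "b", "c")
  xy3 <- cloud_layout(S3)
  d <- as.matrix(dist(xy3))
  expect_lt(d["a", "b"], d["a", "c"])

  # centered at origin
  expect_equal(colMeans(xy3), c(x = 0, y = 0), tolerance = 1e-12)

  # non-symmetric input is an error
  bad <- matrix(c(1, 0.2, 0.8, 1), 2, 2)
  expect_error(cloud_layout(bad), "symmetric")
})

test_that("cloud_layout distances match stats::cmdscale", {
  set.seed(19)
  for (n in 3:5) {
    U <- matrix(runif(n * n), n)
    S <- (U + t(U)) / 2
    diag(S) <- 1
    dimnames(S) <- list(paste0("w", 1:n), paste0("w", 1:n))
    xy <- cloud_layout(S)
    ref <- suppressWarnings(stats::cmdscale(stats::as.dist(1 - S), k = 2))
    expect_lt(max(abs(as.matrix(dist(xy)) - as.matrix(dist(ref)))), 1e-9)
  }
})

test_that("cloud_layout is permutation-equivariant", {
  set.seed(23)
  n <- 5
  U <- matrix(runif(n * n), n)
  S <- (U + t(U)) / 2
  diag(S) <- 1
  dimnames(S) <- list(paste0("w", 1:n), paste0("w", 1:n))
  xy <- cloud_layout(S)
  p <- sample(n)
  xyp <- cloud_layout(S[p, p])
  expect_lt(max(abs(unname(xyp) - unname(xy[p, ]))), 1e-9)
})

test_that("cloud_snapshot composes archive fields with the layout", {
  lex <- lexicon(c("bueno", "malo", "covid"), c(0.8, -0.6, -0.2))
  d1 <- lemma_batch(list(c("bueno", "vacuna"),
                         c("malo", "covid", "vacuna")), "2020-03-01",
                    ids = c("a1", "a2"))
  d2 <- lemma_batch(list(c("vacuna", "bueno"), "vacuna"), "2020-03-02",
                    ids = c("a3", "a4"))
  stream <- rbind(d1, d2)
  res <- run_stream(stream, lex,
                    engine_config(alpha = 0.5, min_learn_occurrences = 2L))

  snap <- cloud_snapshot(res$archive, stream,
                         c("bueno", "vacuna", "malo"),
                         from = "2020-03-01", to = "2020-03-02")
  w <- snap$words
  expect_setequal(w$lemma, c("bueno", "vacuna", "malo"))
  # polarity is the last polarity_after in the window (hand trace)
  expect_equal(w[w$lemma == "bueno"]$polarity, 0.65)
  expect_equal(w[w$lemma == "vacuna"]$polarity, 0.275)
  # frequency is the summed daily_count in the window
  expect_identical(w[w$lemma == "bueno"]$frequency, 2L)
  expect_identical(w[w$lemma == "vacuna"]$frequency, 2L)
  # centroid at the origin
  expect_equal(mean(w$x), 0, tolerance = 1e-12)
  expect_equal(mean(w$y), 0, tolerance = 1e-12)

  # absent word excluded with warning; too few words errors
  expect_warning(
    s2 <- cloud_snapshot(res$archive, stream, c("bueno", "vacuna", "nada"),
                         from = "2020-03-01", to = "2020-03-02"),
    "nada"
  )
  expect_identical(nrow(s2$words), 2L)
  expect_error(
    suppressWarnings(cloud_snapshot(res$archive, stream, c("bueno", "nada"),
                                    from = "2020-03-01", to = "2020-03-02")),
    "at least 2"
  )

  # two consecutive windows on the same vocabulary are diffable
  s_d1 <- cloud_snapshot(res$archive, stream, c("bueno", "malo", "covid"),
                         from = "2020-03-01", to = "2020-03-01")
  expect_setequal(s_d1$words$lemma, c("bueno", "malo", "covid"))
  expect_equal(s_d1$words[s_d1$words$lemma == "bueno"]$polarity, 0.8)
})

test_that("frequency_cloud tallies lemmas with extra stopwords removed", {
  tw <- list(c("vacuna", "cura"), c("vacuna", "covid"), "vacuna")
  fc <- frequency_cloud(tw)
  expect_identical(fc$lemma[1], "vacuna")
  expect_identical(fc$frequency[1], 3L)
  fc2 <- frequency_cloud(tw, extra_stopwords = "covid")
  expect_false("covid" %in% fc2$lemma)
  expect_identical(nrow(frequency_cloud(list())), 0L)
  # brute-force tally agreement
  tab <- sort(table(unlist(tw)), decreasing = TRUE)
  expect_identical(sum(fc$frequency), sum(tab))
})

test_that("rendering maps are pure and monotone", {
  expect_identical(polarity_colour(-1), "#D73027")
  expect_identical(polarity_colour(1), "#1A9850")
  expect_identical(polarity_colour(0), "#BDBDBD")
  # the green-minus-red balance grows monotonically with polarity
  p <- seq(-1, 1, by = 0.25)
  rgbm <- grDevices::col2rgb(polarity_colour(p))
  expect_false(is.unsorted(rgbm["green", ] - rgbm["red", ], strictly = TRUE))
  expect_error(polarity_colour(1.2), "polarity")

  f <- c(0, 1, 10, 100)
  expect_false(is.unsorted(frequency_size(f), strictly = TRUE))
  expect_equal(frequency_size(0, base = 0.8, scale = 0.45), 0.8)
  expect_error(frequency_size(-1), "non-negative")
})
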