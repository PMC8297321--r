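# Visualisation support: co-occurrence counts, PPMI + cosine similarity,
# deterministic classical-MDS word-cloud layout, snapshots and frequency
# clouds. Encoding conventions: position = relatedness (closer = more
# related), colour = polarity (red negative, green positive), size =
# frequency; snapshots at different dates add the time dimension.

#' Tweet-level co-occurrence counts
#'
#' `counts[i, j]` is the number of tweets containing both `vocab[i]` and
#' `vocab[j]` (presence, not multiplicity); the diagonal is each word's
#' tweet frequency. The context unit is the whole tweet: tweets are short,
#' so no sliding window is used.
#'
#' @param tweets a `processed_tweets` table, or a list of lemma vectors.
#' @param vocab non-empty character vector of lemmas (normalized on entry).
#' @return a `cooccurrence_matrix`: `list(vocabulary, counts, doc_count)`.
#' @export
cooccurrence <- function(tweets, vocab) {
  vocab <- normalize_term(vocab)
  if (length(vocab) == 0L) stop("vocab must be non-empty")
  if (anyDuplicated(vocab)) stop("vocab must not contain duplicates")
  ll <- if (is.data.frame(tweets)) tweets$lemmas else tweets
  n <- length(ll)
  X <- matrix(0L, nrow = n, ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    j <- match(unique(ll[[i]]), vocab)
    j <- j[!is.na(j)]
    if (length(j)) X[i, j] <- 1L
  }
  C <- crossprod(X)
  storage.mode(C) <- "integer"
  structure(
    list(vocabulary = vocab, counts = C, doc_count = n),
    class = "cooccurrence_matrix"
  )
}

#' PPMI-weighted cosine similarity
#'
#' Re-weights the co-occurrence counts by positive pointwise mutual
#' information (PPMI), which emphasises informative associations over raw
#' frequency, then takes the cosine similarity between the PPMI rows. Values
#' lie in \[0, 1\]; self-similarity is 1; words with zero occurrences (or no
#' informative association at all) have similarity 0 to all other words.
#'
#' @param M a [cooccurrence()] result.
#' @return a symmetric similarity matrix with the vocabulary as dimnames.
#' @export
ppmi_similarity <- function(M) {
  stopifnot(inherits(M, "cooccurrence_matrix"))
  C <- M$counts
  N <- M$doc_count
  d <- diag(C)
  V <- length(d)
  ppmi <- matrix(0, V, V, dimnames = dimnames(C))
  if (N > 0L) {
    E <- outer(d, d) / N  # expected co-count under independence, times N
    pos <- C > 0L & E > 0
    ppmi[pos] <- pmax(0, log(C[pos] / E[pos]))
  }
  nr <- sqrt(rowSums(ppmi^2))
  S <- matrix(0, V, V, dimnames = dimnames(C))
  nz <- nr > 0
  if (any(nz)) {
    S[nz, nz] <- (ppmi[nz, , drop = FALSE] %*% t(ppmi[nz, , drop = FALSE])) /
      outer(nr[nz], nr[nz])
  }
  S <- pmin(pmax(S, 0), 1)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' Deterministic 2-D word layout by classical MDS
#'
#' Embeds words in the plane so that pairwise distances approximate the
#' dissimilarity `D = 1 - S`: classical (Torgerson) metric multidimensional
#' scaling keeping the top two eigendimensions of the double-centered matrix
#' `-D^2/2`. The configuration is centered at the origin; each axis sign is
#' fixed so that its largest-magnitude coordinate is positive, making the
#' output deterministic up to that convention. Degenerate inputs (rank < 2)
#' are padded with zero coordinates.
#'
#' @param S symmetric similarity matrix with values in \[0, 1\].
#' @param seed ignored (the layout is deterministic); accepted so callers
#'   can treat layout engines interchangeably.
#' @return an `n x 2` matrix of coordinates, rownames from `S`.
#' @export
cloud_layout <- function(S, seed = NULL) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || !isSymmetric(unname(S), tol = 1e-8))
    stop("similarity matrix must be symmetric")
  if (any(S < -1e-9) || any(S > 1 + 1e-9))
    stop("similarity values must lie in [0, 1]")
  n <- nrow(S)
  D <- 1 - S
  diag(D) <- 0
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  coords <- matrix(0, n, 2)
  for (k in 1:2) {
    if (k <= length(e$values) && e$values[k] > 1e-12) {
      coords[, k] <- e$vectors[, k] * sqrt(e$values[k])
    }
  }
  coords <- sweep(coords, 2, colMeans(coords))
  for (k in 1:2) {
    i <- which.max(abs(coords[, k]))
    if (length(i) && coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(S)
  colnames(coords) <- c("x", "y")
  coords
}

#' Build a word-cloud snapshot for a date window
#'
#' For each requested word: polarity = the last archived polarity within the
#' window; frequency = the sum of the archived daily counts within the
#' window; coordinates from [cooccurrence()] -> [ppmi_similarity()] ->
#' [cloud_layout()] over the window's tweets. Words without archive records
#' in the window are excluded with a warning; fewer than two plottable words
#' is an error.
#'
#' @param archive a [sentiment_archive()].
#' @param tweets the `processed_tweets` the archive was computed from (used
#'   for co-occurrence; filtered to the window internally).
#' @param words character vector of words to plot.
#' @param from,to inclusive window bounds (dates).
#' @param country archive country partition to read (default `"all"`).
#' @return a `cloud_snapshot`: `list(from, to, country, words = <data.table
#'   lemma, x, y, polarity, frequency>)`. Coordinates are centered: the
#'   centroid of (x, y) is the origin.
#' @export
cloud_snapshot <- function(archive, tweets, words, from, to, country = "all") {
  from <- as.Date(from); to <- as.Date(to)
  words <- unique(normalize_term(words))
  have <- vapply(words, function(w)
    nrow(get_series(archive, w, country, from, to)) > 0L, NA)
  if (any(!have))
    warning("excluding word(s) with no archive records in window: ",
            paste(words[!have], collapse = ", "))
  words <- words[have]
  if (length(words) < 2L)
    stop("need at least 2 plottable words for a snapshot")

  pol <- vapply(words, function(w) {
    s <- get_series(archive, w, country, from, to)
    s$polarity_after[nrow(s)]
  }, 0)
  freq <- vapply(words, function(w) {
    sub <- archive[archive$lemma == w & archive$country == country &
                     archive$day >= from & archive$day <= to]
    sum(sub$daily_count)
  }, 0)

  tw <- data.table::as.data.table(tweets)
  tw <- tw[day >= from & day <= to]
  S <- ppmi_similarity(cooccurrence(tw, words))
  xy <- cloud_layout(S)

  structure(
    list(from = from, to = to, country = country,
         words = data.table::data.table(
           lemma = words, x = xy[, 1], y = xy[, 2],
           polarity = pol, frequency = as.integer(freq)
         )),
    class = "cloud_snapshot"
  )
}

#' @export
print.cloud_snapshot <- function(x, ...) {
  cat(sprintf("<cloud_snapshot> %s .. %s (%s), %d words\n",
              x$from, x$to, x$country, nrow(x$words)))
  print(x$words)
  invisible(x)
}

#' Word frequencies for a frequency cloud
#'
#' Tallies lemma occurrences over a set of processed tweets (whose lemmas
#' are already base-stopword-free) after removing any extra configured
#' stopwords, and returns them in descending frequency order (ties broken
#' alphabetically for determinism).
#'
#' @param tweets a `processed_tweets` table or list of lemma vectors.
#' @param extra_stopwords additional stopwords (e.g. the pandemic context
#'   words that would otherwise dominate the cloud).
#' @return a data.table `(lemma, frequency)`, descending.
#' @export
frequency_cloud <- function(tweets, extra_stopwords = character()) {
  ll <- if (is.data.frame(tweets)) tweets$lemmas else tweets
  lem <- unlist(ll, use.names = FALSE)
  lem <- remove_stopwords(lem, normalize_term(extra_stopwords))
  if (length(lem) == 0L)
    return(data.table::data.table(lemma = character(), frequency = integer()))
  tab <- table(lem)
  out <- data.table::data.table(lemma = names(tab),
                                frequency = as.integer(tab))
  data.table::setorder(out, -frequency, lemma)
  out[]
}

#' Map polarity to colour
#'
#' Fixed monotone map from polarity to colour: red at -1, neutral grey at 0,
#' green at +1, linearly interpolated.
#'
#' @param polarity numeric vector in \[-1, 1\].
#' @return character vector of hex colours.
#' @export
polarity_colour <- function(polarity) {
  if (any(is.na(polarity)) || any(abs(polarity) > 1))
    stop("polarity must lie in [-1, 1]")
  ramp <- grDevices::colorRamp(c("#D73027", "#BDBDBD", "#1A9850"))
  m <- ramp((polarity + 1) / 2)
  grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
}

#' Map frequency to label size
#'
#' Fixed monotone map, affine in `log(1 + frequency)`.
#'
#' @param frequency non-negative numeric vector.
#' @param base,scale affine coefficients (character expansion units).
#' @return numeric vector of sizes.
#' @export
frequency_size <- function(frequency, base = 0.8, scale = 0.45) {
  if (any(frequency < 0)) stop("frequency must be non-negative")
  base + scale * log1p(frequency)
}

#' Render a cloud snapshot to an image
#'
#' @param snapshot a [cloud_snapshot()].
#' @param file output PNG path (or `NULL` to draw on the active device).
#' @return the snapshot, invisibly.
#' @export
plot_cloud <- function(snapshot, file = NULL) {
  stopifnot(inherits(snapshot, "cloud_snapshot"))
  w <- snapshot$words
  draw <- function() {
    pad <- 0.15 * max(diff(range(w$x)), diff(range(w$y)), 0.1)
    plot(w$x, w$y, type = "n", xlab = "", ylab = "", axes = FALSE,
         xlim = range(w$x) + c(-pad, pad), ylim = range(w$y) + c(-pad, pad),
         main = sprintf("%s .. %s (%s)", snapshot$from, snapshot$to,
                        snapshot$country))
    text(w$x, w$y, labels = w$lemma, col = polarity_colour(w$polarity),
         cex = frequency_size(w$frequency))
  }
  render_to_file(draw, file)
  invisible(snapshot)
}

#' Plot word-sentiment trend series
#'
#' Line plot of archived polarity over time for chosen words (one line per
#' word/country combination).
#'
#' @param archive a [sentiment_archive()].
#' @param words character vector of words.
#' @param countries country partitions to draw.
#' @param file output PNG path (or `NULL` for the active device).
#' @return the long-format series table, invisibly.
#' @export
plot_trends <- function(archive, words, countries = "all", file = NULL) {
  words <- normalize_term(words)
  ser <- data.table::rbindlist(lapply(countries, function(cc) {
    data.table::rbindlist(lapply(words, function(w) {
      s <- get_series(archive, w, cc)
      if (nrow(s) == 0L) return(NULL)
      data.table::data.table(country = cc, lemma = w, s)
    }))
  }))
  if (nrow(ser) > 0L) {
    draw <- function() {
      plot(range(ser$day), c(-1, 1), type = "n", xlab = "day",
           ylab = "polarity", xaxt = "n")
      axis.Date(1, ser$day)
      abline(h = 0, col = "grey80")
      combos <- unique(ser[, list(country, lemma)])
      for (i in seq_len(nrow(combos))) {
        s <- ser[country == combos$country[i] & lemma == combos$lemma[i]]
        lines(s$day, s$polarity_after, col = i, lwd = 2)
      }
      legend("topleft", legend = paste(combos$lemma, combos$country),
             col = seq_len(nrow(combos)), lwd = 2, bty = "n", cex = 0.8)
    }
    render_to_file(draw, file)
  }
  invisible(ser)
}

#' Render a frequency cloud to an image
#'
#' Deterministic spiral placement of the most frequent words, sized by
#' `log(1 + frequency)`.
#'
#' @param freqs a [frequency_cloud()] table.
#' @param file output PNG path (or `NULL` for the active device).
#' @param max_words number of words to draw.
#' @return `freqs`, invisibly.
#' @export
plot_frequency_cloud <- function(freqs, file = NULL, max_words = 50L) {
  f <- utils::head(freqs, max_words)
  if (nrow(f) > 0L) {
    draw <- function() {
      k <- seq_len(nrow(f))
      r <- 0.1 * sqrt(k - 1)
      th <- 2.4 * (k - 1)
      plot(0, 0, type = "n", xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2),
           axes = FALSE, xlab = "", ylab = "")
      text(r * cos(th), r * sin(th), labels = f$lemma,
           cex = frequency_size(f$frequency, base = 0.5, scale = 0.3))
    }
    render_to_file(draw, file)
  }
  invisible(freqs)
}

# Draw to a PNG file when a path is given (skipping gracefully when no PNG
# device is available, e.g. headless builds without cairo), else to the
# active device.
render_to_file <- function(draw, file) {
  if (is.null(file)) {
    draw()
    return(invisible(NULL))
  }
  ok <- tryCatch({
    grDevices::png(file, width = 900, height = 700, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
    TRUE
  }, error = function(e) {
    message("image rendering unavailable (", conditionMessage(e),
            "); skipping ", file)
    FALSE
  })
  invisible(ok)
}
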