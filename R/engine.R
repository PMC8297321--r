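# Sentiment evaluation engine: per-tweet scoring, per-day word-sentiment
# updates via exponential smoothing, and new-word learning.

#' Engine configuration
#'
#' @param alpha daily update weight in (0, 1\]: the new polarity of a word
#'   observed on day `d` is `(1 - alpha) * s_prev + alpha * m_d`, where `m_d`
#'   is the mean sentiment score of that day's tweets containing the word.
#'   `alpha = 1` replaces the old value outright; small values change it
#'   slowly. Default 0.3.
#' @param min_learn_occurrences a word absent from the lexicon is learned on
#'   day `d` only if it appears in at least this many tweets with defined
#'   scores on that day. Default 5.
#' @param learn_enabled switch new-word learning on/off.
#' @return an `engine_config` object.
#' @export
engine_config <- function(alpha = 0.3, min_learn_occurrences = 5L,
                          learn_enabled = TRUE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("alpha must be a number in (0, 1]")
  min_learn_occurrences <- as.integer(min_learn_occurrences)
  if (is.na(min_learn_occurrences) || min_learn_occurrences < 1L)
    stop("min_learn_occurrences must be a positive integer")
  structure(
    list(alpha = alpha, min_learn_occurrences = min_learn_occurrences,
         learn_enabled = isTRUE(learn_enabled)),
    class = "engine_config"
  )
}

#' One exponential-smoothing polarity update
#'
#' The elementary update applied by [daily_update()] to every word observed
#' on a day: a convex combination of the stored value and the day's mean
#' evidence, `s_new = (1 - alpha) * s_prev + alpha * m`. Because it is
#' convex, `s_new` stays in \[-1, 1\] whenever its inputs do, and it moves
#' strictly towards `m` (strengthening when `m > s_prev`, weakening when
#' `m < s_prev`).
#'
#' @param s_prev previous polarity (vectorized).
#' @param m daily mean evidence (vectorized).
#' @param alpha update weight in (0, 1].
#' @return updated polarity vector.
#' @export
update_polarity <- function(s_prev, m, alpha) {
  (1 - alpha) * s_prev + alpha * m
}

#' Score one tweet against a lexicon
#'
#' The tweet score is the arithmetic mean of the lexicon polarities over the
#' matched lemma occurrences (a lemma occurring twice contributes twice).
#' Tweets with no lexicon match have an undefined score (`NA`): they carry
#' no sentiment information and contribute to nothing downstream.
#'
#' @param lemmas character vector of normalized lemmas of one tweet.
#' @param lex a [lexicon()].
#' @return `list(score = <numeric or NA>, matched = <character>)`, with
#'   `matched` the lexicon lemmas found (per occurrence).
#' @examples
#' lex <- lexicon(c("bueno", "malo"), c(0.8, -0.7))
#' score_tweet(c("bueno", "dia", "malo"), lex)
#' @export
score_tweet <- function(lemmas, lex) {
  p <- lex_polarity_vector(lex)[lemmas]
  hit <- !is.na(p)
  list(
    score = if (any(hit)) mean(p[hit]) else NA_real_,
    matched = lemmas[hit]
  )
}

# Score every tweet of a batch against a fixed polarity vector.
# Returns per-tweet scores and the unique (tweet, lemma) presence pairs.
score_batch <- function(lemma_list, pol) {
  n <- length(lemma_list)
  scores <- rep(NA_real_, n)
  pres <- data.table::data.table(idx = integer(), lemma = character())
  if (n == 0L) return(list(scores = scores, presence = pres))
  cnt <- lengths(lemma_list)
  if (sum(cnt) == 0L) return(list(scores = scores, presence = pres))
  occ <- data.table::data.table(
    idx = rep.int(seq_len(n), cnt),
    lemma = unlist(lemma_list, use.names = FALSE)
  )
  occ[, polarity := unname(pol[lemma])]
  sc <- occ[!is.na(polarity), list(score = mean(polarity)), by = idx]
  scores[sc$idx] <- sc$score
  pres <- unique(occ[, list(idx, lemma)])
  list(scores = scores, presence = pres)
}

check_single_day <- function(batch) {
  d <- unique(batch$day)
  if (length(d) != 1L)
    stop("batch must contain tweets from exactly one day; got ",
         length(d), " distinct days")
  d
}

#' Daily word-sentiment update
#'
#' For each lexicon word `w` detected in at least one defined-score tweet of
#' day `d`, computes the daily mean evidence `m_w(d)` (mean of the scores of
#' the tweets containing `w`; a tweet counts once however often it repeats
#' the word) and updates the stored polarity with [update_polarity()]. All
#' tweets are scored against the lexicon state at the start of the day, so
#' results do not depend on within-day tweet order. Words not observed on
#' day `d` keep their polarity and emit no record. The word's
#' `total_frequency` grows by its defined-score tweet count `n_w(d)`.
#'
#' @param batch a `processed_tweets` table whose rows all share one day.
#' @param lex the start-of-day [lexicon()].
#' @param cfg an [engine_config()].
#' @param .scores internal: precomputed [score_batch] result.
#' @return `list(lexicon = <updated lexicon>, records = <data.table>)` with
#'   one record per updated word: `lemma`, `day`, `polarity_after`,
#'   `daily_mean`, `daily_count`.
#' @export
daily_update <- function(batch, lex, cfg = engine_config(), .scores = NULL) {
  batch <- data.table::as.data.table(batch)
  d <- check_single_day(batch)
  sb <- .scores %||% score_batch(batch$lemmas, lex_polarity_vector(lex))
  defined <- which(!is.na(sb$scores))
  pres <- sb$presence[idx %in% defined & lemma %in% lex$lemma]
  if (nrow(pres) == 0L) {
    return(list(lexicon = lex, records = empty_records()))
  }
  ev <- pres[, list(m = mean(sb$scores[idx]), n = .N), by = lemma]
  data.table::setorder(ev, lemma)

  lex2 <- new_lexicon(data.table::copy(lex))
  i <- match(ev$lemma, lex2$lemma)
  s_new <- update_polarity(lex2$polarity[i], ev$m, cfg$alpha)
  data.table::set(lex2, i, "polarity", s_new)
  data.table::set(lex2, i, "total_frequency",
                  lex2$total_frequency[i] + as.integer(ev$n))

  records <- data.table::data.table(
    lemma = ev$lemma, day = d, polarity_after = s_new,
    daily_mean = ev$m, daily_count = as.integer(ev$n)
  )
  list(lexicon = lex2, records = records)
}

empty_records <- function() {
  data.table::data.table(
    lemma = character(), day = as.Date(character()),
    polarity_after = numeric(), daily_mean = numeric(),
    daily_count = integer()
  )
}

#' Learn new words from a day's tweets
#'
#' Runs after [daily_update()] for the same day. Every lemma absent from the
#' lexicon that appears in at least `cfg$min_learn_occurrences` tweets with
#' defined scores on day `d` is inserted with polarity equal to the mean of
#' those tweets' scores, `origin = "learned"` and `created_on = d`. Learned
#' words participate in scoring only from the next day onward.
#'
#' @inheritParams daily_update
#' @return the augmented [lexicon()].
#' @export
learn_new_words <- function(batch, lex, cfg = engine_config(), .scores = NULL) {
  if (!cfg$learn_enabled) return(lex)
  batch <- data.table::as.data.table(batch)
  d <- check_single_day(batch)
  sb <- .scores %||% score_batch(batch$lemmas, lex_polarity_vector(lex))
  defined <- which(!is.na(sb$scores))
  pres <- sb$presence[idx %in% defined & !(lemma %in% lex$lemma)]
  if (nrow(pres) == 0L) return(lex)
  ev <- pres[, list(m = mean(sb$scores[idx]), n = .N), by = lemma]
  ev <- ev[n >= cfg$min_learn_occurrences]
  if (nrow(ev) == 0L) return(lex)
  data.table::setorder(ev, lemma)
  new_entries <- data.table::data.table(
    lemma = ev$lemma, polarity = ev$m, origin = "learned",
    created_on = d, total_frequency = as.integer(ev$n)
  )
  new_lexicon(rbind(data.table::as.data.table(lex), new_entries))
}

#' Run the engine over a multi-day stream
#'
#' Orchestrates the daily loop: days are processed in strictly increasing
#' order; within each day all tweets are scored against the start-of-day
#' lexicon, then [daily_update()] adjusts the polarities of observed words,
#' then [learn_new_words()] inserts qualifying unknown words (visible to
#' scoring from the next day). Unsorted input is sorted internally; within a
#' day, tweet order has no effect on any output. Polarities of words
#' unobserved on a day persist unchanged (no decay).
#'
#' @param tweets a `processed_tweets` table (any number of days).
#' @param lex the seed [lexicon()].
#' @param cfg an [engine_config()].
#' @param country label stored in the archive records (use one engine run
#'   per country partition, or `"all"` for a pooled run).
#' @return `list(archive = <sentiment_archive>, lexicon = <final lexicon>)`.
#' @export
run_stream <- function(tweets, lex, cfg = engine_config(), country = "all") {
  tweets <- data.table::as.data.table(tweets)
  if (nrow(tweets) == 0L)
    return(list(archive = sentiment_archive(), lexicon = lex))
  days <- sort(unique(tweets$day))
  recs <- vector("list", length(days))
  for (k in seq_along(days)) {
    batch <- tweets[day == days[k]]
    sb <- score_batch(batch$lemmas, lex_polarity_vector(lex))
    du <- daily_update(batch, lex, cfg, .scores = sb)
    lex <- learn_new_words(batch, du$lexicon, cfg, .scores = sb)
    recs[[k]] <- du$records
  }
  all_recs <- data.table::rbindlist(recs)
  if (nrow(all_recs) > 0L) all_recs[, country := country]
  list(archive = sentiment_archive(all_recs), lexicon = lex)
}
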