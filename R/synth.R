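# Synthetic tweet-stream generator with planted per-word sentiment
# trajectories, plus recovery metrics. Every pipeline stage is testable with
# no external data: each planted tweet carries a context keyword, a topic
# keyword, the trajectory word, four filler lexicon words and one "adjuster"
# lexicon word chosen so the tweet's matched-lemma mean lands on the planted
# value (up to the lexicon grid resolution and the per-tweet noise).

#' Specify a planted sentiment trajectory
#'
#' @param lemma the trajectory word (letters only; it must *not* be in the
#'   seed lexicon -- the engine learns it from the stream, which is exactly
#'   what the recovery test exercises).
#' @param shape `"constant"`, `"linear"` (start to end across the run) or
#'   `"step"` (start before `step_day`, end from `step_day` on).
#' @param start_value,end_value planted polarities in \[-1, 1\].
#' @param step_day day index of the step (required for `shape = "step"`).
#' @param tweets_per_day tweets emitted per day, country and word.
#' @return a `trajectory_spec`.
#' @export
trajectory_spec <- function(lemma, shape = c("constant", "linear", "step"),
                            start_value, end_value = start_value,
                            step_day = NULL, tweets_per_day = 200L) {
  shape <- match.arg(shape)
  lemma <- normalize_term(lemma)
  if (!grepl("^\\p{L}{2,}$", lemma, perl = TRUE))
    stop("trajectory lemma must be a single word of letters")
  if (abs(start_value) > 1 || abs(end_value) > 1)
    stop("planted values must lie in [-1, 1]")
  if (shape == "step" && is.null(step_day))
    stop("shape 'step' requires step_day")
  structure(
    list(lemma = lemma, shape = shape, start_value = start_value,
         end_value = end_value, step_day = step_day,
         tweets_per_day = as.integer(tweets_per_day)),
    class = "trajectory_spec"
  )
}

#' Planted trajectory value
#'
#' @param spec a [trajectory_spec()].
#' @param day_index integer day index (1-based), vectorized.
#' @param n_days total days of the run.
#' @return planted polarity mu(day) vector.
#' @export
trajectory_value <- function(spec, day_index, n_days) {
  switch(spec$shape,
    constant = rep(spec$start_value, length(day_index)),
    linear = if (n_days == 1L) rep(spec$start_value, length(day_index)) else
      spec$start_value + (spec$end_value - spec$start_value) *
        (day_index - 1) / (n_days - 1),
    step = ifelse(day_index < spec$step_day, spec$start_value, spec$end_value)
  )
}

#' Generate a synthetic fixture lexicon
#'
#' `n` synthetic letter-only lemmas with polarities on the uniform grid over
#' \[-1, 1\] (resolution `2 / (n - 1)`), so that any target tweet mean is
#' approximable by an adjuster word to half the grid resolution. Lemma names
#' end in a vowel so the default lemmatizer leaves them untouched.
#'
#' @param n number of entries, at least 21.
#' @param seed unused at present (the grid is deterministic); kept so the
#'   signature matches the other generators.
#' @return a [lexicon()].
#' @export
generate_fixture_lexicon <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 21L)
    stop("n must be at least 21: a coarser polarity grid cannot support ",
         "adjuster selection")
  lexicon(synth_lemmas(n), seq(-1, 1, length.out = n))
}

synth_lemmas <- function(n, prefix = "lex") {
  combos <- expand.grid(a = letters, b = letters, stringsAsFactors = FALSE)
  if (n > nrow(combos)) stop("too many synthetic lemmas requested")
  paste0(prefix, combos$a[seq_len(n)], combos$b[seq_len(n)], "o")
}

# Letter-only encoding of a day index, so block lemmas stay alphabetic.
day_code <- function(d) {
  paste0(letters[(d - 1L) %/% 26L + 1L], letters[(d - 1L) %% 26L + 1L])
}

evidence_block <- function(word, d, n_grid) {
  synth_lemmas(n_grid, prefix = paste0(word, "flr", day_code(d)))
}

#' Build the scenario seed lexicon
#'
#' The evidence vocabulary of the generated stream is partitioned per
#' trajectory word *and per day*: each (word, day) block is a fresh copy of
#' the polarity grid, used only on that day. Evidence words therefore still
#' hold their seed polarities when they are used, so every tweet's
#' matched-lemma mean equals the planted value up to grid resolution and
#' noise -- without the partition, the engine's own updates to shared
#' evidence words echo one word's smoothing lag into every other word's
#' evidence, and recovery measures that contamination rather than the
#' engine. A shared background block serves the background tweets (which
#' never reach the engine).
#'
#' @param cfg a [synth_config()].
#' @return a [lexicon()] with one grid block per (trajectory word, day) plus
#'   one background block.
#' @export
scenario_lexicon <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$filler_lexicon_size
  grid <- seq(-1, 1, length.out = n)
  lemmas <- character(0)
  for (tr in cfg$trajectories) {
    for (d in seq_len(cfg$n_days)) {
      lemmas <- c(lemmas, evidence_block(tr$lemma, d, n))
    }
  }
  lemmas <- c(lemmas, synth_lemmas(n, prefix = "bgflr"))
  lexicon(lemmas, rep_len(grid, length(lemmas)))
}

#' Synthetic stream configuration
#'
#' Defaults define the package's reference recovery scenario: 60 days, one
#' country, 200 tweets per day and word, per-tweet Gaussian noise with sd
#' 0.05 on the planted value, an 81-word fixture lexicon (grid resolution
#' 0.025), and three planted trajectories covering the three shapes --
#' a rising linear word ("vacuna", -0.6 to 0.6), a constant positive word
#' ("reunion", 0.5) and a downward step word ("mascarilla", 0.4 to -0.4 at
#' day 30).
#'
#' @param seed RNG seed; a fixed seed makes the stream fully reproducible.
#' @param n_days number of calendar days.
#' @param countries country codes; trajectory tweets are emitted per country.
#' @param start_date first calendar day.
#' @param context_keywords context-stage keywords planted in every
#'   trajectory tweet (first element used).
#' @param topic_vocab named list topic -> keyword(s) (first keyword planted).
#' @param word_topics named character: trajectory lemma -> topic name.
#' @param filler_lexicon_size fixture lexicon size (>= 21).
#' @param noise_sd per-tweet Gaussian noise sd on the planted value.
#' @param trajectories list of [trajectory_spec()].
#' @param background_tweets_per_day tweets per day with filler words only and
#'   no context keyword (they must be dropped by the context filter).
#' @param filler_window fillers are sampled from lexicon words within this
#'   polarity distance of the tweet's target, which keeps the adjuster
#'   within \[-1, 1\] for all but extreme noise draws.
#' @return a `synth_config`.
#' @export
synth_config <- function(seed = 42L,
                         n_days = 60L,
                         countries = "ES",
                         start_date = as.Date("2020-03-01"),
                         context_keywords = c("covid", "covid19", "coronavirus"),
                         topic_vocab = list(vaccines = "pfizer",
                                            employment = "desempleo",
                                            health = "estres"),
                         word_topics = c(vacuna = "vaccines",
                                         reunion = "employment",
                                         mascarilla = "health"),
                         filler_lexicon_size = 81L,
                         noise_sd = 0.05,
                         trajectories = list(
                           trajectory_spec("vacuna", "linear", -0.6, 0.6),
                           trajectory_spec("reunion", "constant", 0.5),
                           trajectory_spec("mascarilla", "step", 0.4, -0.4,
                                           step_day = 30L)
                         ),
                         background_tweets_per_day = 50L,
                         filler_window = 0.1) {
  cfg <- list(
    seed = as.integer(seed), n_days = as.integer(n_days),
    countries = toupper(countries), start_date = as.Date(start_date),
    context_keywords = normalize_term(context_keywords),
    topic_vocab = lapply(topic_vocab, normalize_term),
    word_topics = stats::setNames(as.character(word_topics),
                                  normalize_term(names(word_topics))),
    filler_lexicon_size = as.integer(filler_lexicon_size),
    noise_sd = noise_sd,
    trajectories = trajectories,
    background_tweets_per_day = as.integer(background_tweets_per_day),
    filler_window = filler_window
  )
  if (cfg$n_days < 0L) stop("n_days must be >= 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  for (tr in cfg$trajectories) {
    stopifnot(inherits(tr, "trajectory_spec"))
    if (!(tr$lemma %in% names(cfg$word_topics)))
      stop("trajectory word '", tr$lemma, "' has no topic in word_topics")
  }
  structure(cfg, class = "synth_config")
}

#' Read a synthetic-stream configuration from JSON
#'
#' Accepts the [synth_config()] fields, with `trajectories` as an array of
#' objects (`lemma`, `shape`, `start_value`, `end_value`, `step_day`,
#' `tweets_per_day`).
#'
#' @param path JSON file path.
#' @return a `synth_config`.
#' @export
synth_config_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!is.null(raw$trajectories))
    raw$trajectories <- lapply(raw$trajectories, function(tr)
      do.call(trajectory_spec, tr))
  if (!is.null(raw$word_topics)) raw$word_topics <- unlist(raw$word_topics)
  if (!is.null(raw$topic_vocab))
    raw$topic_vocab <- lapply(raw$topic_vocab, unlist)
  do.call(synth_config, raw)
}

#' The reference recovery scenario
#'
#' The default [synth_config()]: the fixed stated world against which
#' trajectory recovery is measured (seed 42).
#'
#' @return a `synth_config`.
#' @export
default_recovery_scenario <- function() synth_config()

#' Generate a synthetic tweet stream with planted trajectories
#'
#' For each trajectory word, day and country, emits `tweets_per_day` tweets
#' each containing a context keyword, a topic keyword, the word itself, four
#' filler lexicon lemmas (sampled from the word's fresh evidence block for
#' that day, within `filler_window` of the target) and one adjuster lexicon
#' lemma chosen so the mean seed polarity of the tweet's (filler + adjuster)
#' lexicon matches equals `clip(mu(day) + eps, -1, 1)` with
#' `eps ~ N(0, noise_sd)`. Unreachable adjuster targets are clipped and
#' counted. Background tweets contain random background-block fillers only
#' (no context keyword), so the context filter must drop them. A fixed seed
#' makes the output byte-identical across runs.
#'
#' Some tweets carry decorations (a mention, an emoji, a hashtag) so the
#' cleaning stage is exercised end to end; decorations never add lexicon or
#' keyword tokens beyond the planted design.
#'
#' @param cfg a [synth_config()].
#' @param lex the seed [lexicon()] for the scenario; defaults to
#'   [scenario_lexicon()] of `cfg`, which contains the per-(word, day)
#'   evidence blocks the generator draws from.
#' @return `list(tweets = <raw tweet data.table>, truth = <data.table lemma,
#'   country, day, mu>, n_clipped = <integer>)`.
#' @export
generate_stream <- function(cfg, lex = scenario_lexicon(cfg)) {
  stopifnot(inherits(cfg, "synth_config"))
  validate_lexicon(lex)
  n_grid <- cfg$filler_lexicon_size
  grid <- seq(-1, 1, length.out = n_grid)
  ctx <- cfg$context_keywords[1L]
  bg_lemmas <- synth_lemmas(n_grid, prefix = "bgflr")

  withr::with_seed(cfg$seed, {
    tw_parts <- list()
    truth_parts <- list()
    n_clipped <- 0L
    counter <- 0L

    for (tr in cfg$trajectories) {
      topic_kw <- cfg$topic_vocab[[cfg$word_topics[[tr$lemma]]]][1L]
      for (cc in cfg$countries) {
        for (d in seq_len(cfg$n_days)) {
          glem <- evidence_block(tr$lemma, d, n_grid)
          if (!all(glem %in% lex$lemma))
            stop("lexicon lacks the evidence block for '", tr$lemma,
                 "', day ", d, "; build it with scenario_lexicon(cfg)")
          mu <- trajectory_value(tr, d, cfg$n_days)
          date <- cfg$start_date + d - 1L
          tpd <- tr$tweets_per_day
          eps <- stats::rnorm(tpd, 0, cfg$noise_sd)
          tgt <- pmin(1, pmax(-1, mu + eps))
          texts <- character(tpd)
          for (i in seq_len(tpd)) {
            cand <- which(abs(grid - tgt[i]) <= cfg$filler_window)
            fil <- cand[sample.int(length(cand), 4L, replace = TRUE)]
            a_star <- 5 * tgt[i] - 4 * mean(grid[fil])
            if (abs(a_star) > 1) {
              n_clipped <- n_clipped + 1L
              a_star <- sign(a_star)
            }
            adj <- which.min(abs(grid - a_star))
            words <- c(ctx, topic_kw, tr$lemma, glem[fil], glem[adj])
            txt <- paste(words, collapse = " ")
            if (i %% 5L == 0L) txt <- paste("@amigo", txt)
            if (i %% 7L == 0L) txt <- paste0(txt, " \U0001F637")
            if (i %% 9L == 0L) txt <- paste0(txt, " #QuedateEnCasa")
            texts[i] <- txt
          }
          ids <- sprintf("s%08d", counter + seq_len(tpd))
          counter <- counter + tpd
          tw_parts[[length(tw_parts) + 1L]] <- data.table::data.table(
            id = ids,
            created_at = sprintf("%sT%02d:%02d:00Z", format(date),
                                 (seq_len(tpd) - 1L) %% 24L,
                                 (seq_len(tpd) * 7L) %% 60L),
            text = texts,
            country_code = cc
          )
          truth_parts[[length(truth_parts) + 1L]] <- data.table::data.table(
            lemma = tr$lemma, country = cc, day = date, mu = mu
          )
        }
      }
    }

    if (cfg$background_tweets_per_day > 0L && cfg$n_days > 0L) {
      for (d in seq_len(cfg$n_days)) {
        date <- cfg$start_date + d - 1L
        nb <- cfg$background_tweets_per_day
        texts <- vapply(seq_len(nb), function(i) {
          fil <- sample.int(length(bg_lemmas), 4L, replace = TRUE)
          paste(bg_lemmas[fil], collapse = " ")
        }, "")
        ids <- sprintf("s%08d", counter + seq_len(nb))
        counter <- counter + nb
        tw_parts[[length(tw_parts) + 1L]] <- data.table::data.table(
          id = ids,
          created_at = sprintf("%sT%02d:30:00Z", format(date),
                               (seq_len(nb) - 1L) %% 24L),
          text = texts,
          country_code = rep_len(cfg$countries, nb)
        )
      }
    }

    tweets <- if (length(tw_parts)) data.table::rbindlist(tw_parts) else
      data.table::data.table(id = character(), created_at = character(),
                             text = character(), country_code = character())
    truth <- if (length(truth_parts)) data.table::rbindlist(truth_parts) else
      data.table::data.table(lemma = character(), country = character(),
                             day = as.Date(character()), mu = numeric())
    if (n_clipped > 0L)
      message(sprintf("%d adjuster target(s) outside [-1, 1] were clipped",
                      n_clipped))
    list(tweets = tweets, truth = truth, n_clipped = n_clipped)
  })
}

#' Trajectory recovery metrics
#'
#' Compares each planted trajectory with the corresponding recovered series
#' in the archive: Pearson correlation and root-mean-square error over the
#' days present in both. Fewer than three common days, or a planted/recovered
#' series with zero variance (Pearson undefined), flags the metric; RMSE is
#' still reported whenever common days exist.
#'
#' @param truth ground-truth table from [generate_stream()] (`lemma`,
#'   `country`, `day`, `mu`).
#' @param archive the [sentiment_archive()] produced by running the pipeline
#'   on the generated stream.
#' @return a data.table with one row per (lemma, country): `n_common`,
#'   `pearson_r`, `rmse`, `flagged`.
#' @export
recovery_metrics <- function(truth, archive) {
  truth <- data.table::as.data.table(truth)
  combos <- unique(truth[, list(lemma, country)])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    w <- combos$lemma[i]
    cc <- combos$country[i]
    planted <- truth[lemma == w & country == cc]
    ser <- get_series(archive, w, cc)
    mg <- merge(planted[, list(day, mu)], ser, by = "day")
    n <- nrow(mg)
    if (n < 3L) {
      return(data.table::data.table(
        lemma = w, country = cc, n_common = n,
        pearson_r = NA_real_, rmse = if (n > 0L)
          sqrt(mean((mg$mu - mg$polarity_after)^2)) else NA_real_,
        flagged = TRUE
      ))
    }
    rmse <- sqrt(mean((mg$mu - mg$polarity_after)^2))
    undef <- stats::sd(mg$mu) == 0 || stats::sd(mg$polarity_after) == 0
    data.table::data.table(
      lemma = w, country = cc, n_common = n,
      pearson_r = if (undef) NA_real_ else stats::cor(mg$mu, mg$polarity_after),
      rmse = rmse, flagged = undef
    )
  })
  data.table::rbindlist(out)
}

#' Run the reference recovery scenario end to end
#'
#' Generates the synthetic stream, pushes it through the full pipeline
#' (three-stage filter with the context and topic keywords configured as
#' extra stopwords so they never reach the engine, then the daily engine per
#' country) and computes [recovery_metrics()].
#'
#' @param cfg a [synth_config()] (default: the reference scenario).
#' @param engine an [engine_config()] (default alpha 0.3, learning on).
#' @return list with `metrics`, `archive`, `truth`, `counts`, `lexicon`
#'   (final state), `retained` (filtered processed tweets) and `n_input`.
#' @export
run_recovery_scenario <- function(cfg = default_recovery_scenario(),
                                  engine = engine_config(alpha = 0.3,
                                                         min_learn_occurrences = 5L)) {
  lex <- scenario_lexicon(cfg)
  gen <- generate_stream(cfg, lex)

  context <- rule_set("context", cfg$context_keywords)
  topics <- lapply(stats::setNames(names(cfg$topic_vocab),
                                   names(cfg$topic_vocab)),
                   function(nm) rule_set(nm, cfg$topic_vocab[[nm]]))
  # keywords are configured as extra stopwords (in surface and lemmatized
  # form) so they never reach the engine as shared pseudo-words
  kw <- c(cfg$context_keywords, unlist(cfg$topic_vocab, use.names = FALSE))
  stop_extra <- unique(c(spanish_stopwords(), kw, default_lemmatizer(kw)))
  fl <- filter_stream(gen$tweets, context, topics, cfg$countries,
                      stopwords = stop_extra)

  arch_parts <- list()
  final_lex <- lex
  for (cc in cfg$countries) {
    sub <- fl$tweets[fl$tweets$country_code == cc]
    res <- run_stream(sub, lex, engine, country = cc)
    arch_parts[[cc]] <- data.table::as.data.table(res$archive)
    final_lex <- res$lexicon
  }
  archive <- sentiment_archive(data.table::rbindlist(arch_parts))

  list(
    metrics = recovery_metrics(gen$truth, archive),
    archive = archive, truth = gen$truth, counts = fl$counts,
    lexicon = final_lex, retained = fl$tweets, n_input = nrow(gen$tweets)
  )
}
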