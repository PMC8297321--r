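# Shared fixture builders. Everything is generated in code; no stored data.

tiny_lexicon <- function() {
  lexicon(c("bueno", "malo", "covid"), c(0.8, -0.7, -0.2))
}

# Raw tweet records, one list per tweet, assembled into a data.table.
raw_tweets <- function(texts, days, countries = "ES", ids = NULL) {
  n <- length(texts)
  data.table::data.table(
    id = ids %||% sprintf("t%03d", seq_len(n)),
    created_at = paste0(rep_len(as.character(days), n), "T12:00:00Z"),
    text = texts,
    country_code = rep_len(countries, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A processed-tweets table built directly from lemma lists (bypassing text
# processing) for engine-level tests.
lemma_batch <- function(lemma_lists, day, ids = NULL, country = "ES") {
  n <- length(lemma_lists)
  out <- data.table::data.table(
    id = ids %||% sprintf("b%03d", seq_len(n)),
    day = rep(as.Date(day), n),
    country_code = rep_len(country, n),
    clean_text = vapply(lemma_lists, paste, "", collapse = " "),
    tokens = lemma_lists,
    lemmas = lemma_lists,
    topics = rep(list(character(0)), n)
  )
  data.table::setattr(out, "class",
                      c("processed_tweets", "data.table", "data.frame"))
  out
}

# Small synthetic scenario for pipeline-level tests (fast; structure, not
# statistics).
small_synth_config <- function(seed = 7L) {
  synth_config(
    seed = seed, n_days = 15L, countries = c("ES", "MX"),
    trajectories = list(
      trajectory_spec("vacuna", "linear", -0.6, 0.6, tweets_per_day = 30L),
      trajectory_spec("reunion", "constant", 0.5, tweets_per_day = 30L)
    ),
    word_topics = c(vacuna = "vaccines", reunion = "employment"),
    background_tweets_per_day = 10L
  )
}

scenario_stopwords <- function(cfg) {
  kw <- c(cfg$context_keywords, unlist(cfg$topic_vocab, use.names = FALSE))
  unique(c(spanish_stopwords(), kw, default_lemmatizer(kw)))
}

# Materialise a scenario on disk (stream + lexicon + pipeline config) for
# run_all / CLI tests.
write_scenario_inputs <- function(dir, cfg = small_synth_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lex <- scenario_lexicon(cfg)
  gen <- generate_stream(cfg, lex)
  write_tweets_jsonl(gen$tweets, file.path(dir, "stream.jsonl"))
  save_lexicon(lex, file.path(dir, "lexicon.tsv"))
  kw <- c(cfg$context_keywords, unlist(cfg$topic_vocab, use.names = FALSE))
  config <- list(
    input = file.path(dir, "stream.jsonl"),
    lexicon = file.path(dir, "lexicon.tsv"),
    output_dir = file.path(dir, "out"),
    extra_stopwords = unique(c(kw, default_lemmatizer(kw))),
    rules = list(
      context = cfg$context_keywords,
      topics = cfg$topic_vocab,
      countries = cfg$countries
    ),
    engine = list(alpha = 0.3, min_learn_occurrences = 5, learn_enabled = TRUE),
    viz = list(words = names(cfg$word_topics), window_days = 10),
    seed = 1
  )
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  list(config_path = cfg_path, cfg = cfg, gen = gen)
}

scenario_rules <- function(cfg) {
  list(
    context = rule_set("context", cfg$context_keywords),
    topics = lapply(stats::setNames(names(cfg$topic_vocab),
                                    names(cfg$topic_vocab)),
                    function(nm) rule_set(nm, cfg$topic_vocab[[nm]]))
  )
}
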