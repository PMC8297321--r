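# Tweet cleaning and linguistic processing: remove non-linguistic tokens,
# tokenize, lemmatize, drop stopwords.

#' Clean raw tweet text
#'
#' Applies, in order: removal of URLs, of `@`-mentions (the whole token), of
#' `#`-hashtags (the whole token, including the word after `#`), of
#' emoji/smiley codepoints, and of all remaining non-letter special
#' characters; finally collapses whitespace runs and trims. Case is
#' preserved; normalization happens at tokenization.
#'
#' @param text character vector of raw tweet texts.
#' @param keep_hashtag_word keep the word following `#` instead of dropping
#'   the whole hashtag token (off by default).
#' @return character vector of cleaned texts. Never longer than the input.
#' @examples
#' clean_text("@usuario Vacuna ya! \U0001F637 #covid https://t.co/x")
#' @export
clean_text <- function(text, keep_hashtag_word = FALSE) {
  if (length(text) == 0L) return(character(0))
  x <- enc2utf8(as.character(text))
  x <- gsub("(?i)\\b(?:https?://|www\\.)\\S+", " ", x, perl = TRUE)
  x <- gsub("(^|\\s)@\\S+", " ", x, perl = TRUE)
  if (keep_hashtag_word) {
    x <- gsub("#", " ", x, fixed = TRUE)
  } else {
    x <- gsub("(^|\\s)#\\S+", " ", x, perl = TRUE)
  }
  # emoji / smiley / pictographic codepoints and variation selectors
  x <- gsub(paste0(
    "(*UTF)[\\x{1F000}-\\x{1FAFF}",       # pictographs, emoticons, symbols
    "\\x{2190}-\\x{21FF}\\x{2600}-\\x{27BF}", # arrows, misc symbols, dingbats
    "\\x{2B00}-\\x{2BFF}\\x{2764}",           # misc symbols/arrows, heavy heart
    "\\x{FE00}-\\x{FE0F}\\x{200D}]"           # variation selectors, ZWJ
  ), " ", x, perl = TRUE)
  x <- gsub("[^\\p{L}\\s]", " ", x, perl = TRUE)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

#' Tokenize cleaned text
#'
#' Splits on any non-letter character, normalizes each token with
#' [normalize_term()], and drops tokens shorter than two letters (single
#' letters and digit-only fragments carry no lexical information here).
#'
#' @param text a single character string (for vectors, see
#'   [process_stream()], which tokenizes the whole stream at once).
#' @return character vector of normalized tokens (possibly empty).
#' @examples
#' tokenize("Vacuna ya")
#' tokenize("covid-19")
#' @export
tokenize <- function(text) {
  stopifnot(length(text) <= 1L)
  if (length(text) == 0L || is.na(text)) return(character(0))
  tokenize_many(text)[[1L]]
}

tokenize_many <- function(texts) {
  texts <- normalize_term(texts)
  parts <- strsplit(texts, "[^\\p{L}]+", perl = TRUE)
  lapply(parts, function(p) p[nchar(p) >= 2L])
}

# Spanish forms that look plural but are not, or whose plural is irregular.
es_invariant <- c(
  "crisis", "virus", "gracias", "pais", "mes", "tos", "dios", "dosis",
  "analisis", "lunes", "martes", "miercoles", "jueves", "viernes", "caos",
  "pues", "tres", "seis"
)
es_irregular <- c(
  meses = "mes", paises = "pais", veces = "vez", luces = "luz", peces = "pez",
  cruces = "cruz", voces = "voz", raices = "raiz"
)

#' Rule-based default lemmatizer
#'
#' A download-free suffix stripper serving as the bundled lemmatizer: strips
#' the Spanish plural suffixes `-es` (after a consonant other than `s`) and
#' `-s` (otherwise) when the remaining stem has at least three letters, with
#' a small table of invariant and irregular forms. It is deliberately
#' shallow -- a stemmer standing in for full morphological analysis -- and
#' can be replaced by any `function(tokens) -> lemmas` via the `lemmatizer`
#' argument of [lemmatize()], [process_stream()] and [filter_stream()].
#'
#' @param tokens character vector of normalized tokens.
#' @return character vector of lemmas, same length.
#' @examples
#' default_lemmatizer(c("vacunas", "hospitales", "clases", "covid"))
#' @export
default_lemmatizer <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  out <- tokens
  irr <- es_irregular[tokens]
  has_irr <- !is.na(irr)
  out[has_irr] <- irr[has_irr]
  todo <- which(!has_irr & !(tokens %in% es_invariant))
  t2 <- out[todo]
  n <- nchar(t2)
  last1 <- substr(t2, n, n)
  last2 <- substr(t2, n - 1L, n)
  prev <- substr(t2, n - 2L, n - 2L)
  vowels <- c("a", "e", "i", "o", "u")
  strip_es <- last2 == "es" & (n - 2L) >= 3L & !(prev %in% c(vowels, "s"))
  t2[strip_es] <- substr(t2[strip_es], 1L, n[strip_es] - 2L)
  strip_s <- !strip_es & last1 == "s" & (n - 1L) >= 3L
  t2[strip_s] <- substr(t2[strip_s], 1L, n[strip_s] - 1L)
  out[todo] <- t2
  out
}

#' Lemmatize tokens
#'
#' Maps each token through the active lemmatizer (an injectable
#' `function(tokens) -> lemmas`; the default is [default_lemmatizer()]).
#'
#' @param tokens character vector of normalized tokens.
#' @param lemmatizer the lemmatizer function.
#' @return character vector of lemmas.
#' @export
lemmatize <- function(tokens, lemmatizer = default_lemmatizer) {
  lemmatizer(tokens)
}

#' Remove stopwords
#'
#' Order-preserving removal of every lemma belonging to the stopword set
#' (the base Spanish list plus any configured domain extras, e.g.
#' pandemic-context words that would otherwise dominate every tweet).
#'
#' @param lemmas character vector of normalized lemmas.
#' @param stopwords character vector of pre-normalized stopwords.
#' @return `lemmas` without stopword members, order preserved.
#' @export
remove_stopwords <- function(lemmas, stopwords) {
  lemmas[!(lemmas %in% stopwords)]
}

#' Bundled Spanish stopword list
#'
#' Returns the package's base Spanish stopword list (function words,
#' auxiliaries, common adverbs; diacritics pre-folded to match
#' [normalize_term()] output). Extend it with `c(spanish_stopwords(),
#' extra)` or via [load_stopwords()].
#'
#' @return character vector of normalized stopwords.
#' @export
spanish_stopwords <- function() {
  path <- system.file("extdata", "stopwords_es.txt", package = "sentidrift")
  .stopword_cache$base %||% {
    sw <- load_stopwords(path)
    .stopword_cache$base <- sw
    sw
  }
}

.stopword_cache <- new.env(parent = emptyenv())
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a stopword list from a plain-text file
#'
#' One term per line; blank lines and `#` comment lines ignored; terms are
#' normalized.
#'
#' @param path file path.
#' @return character vector of normalized stopwords.
#' @export
load_stopwords <- function(path) {
  if (!file.exists(path)) stop("stopword file not found: ", path)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- normalize_term(x)
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

parse_utc <- function(x) {
  x <- as.character(x)
  y <- sub("Z$", "", sub("T", " ", x, fixed = TRUE))
  ts <- as.POSIXct(y, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  date_only <- is.na(ts) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  ts[date_only] <- as.POSIXct(x[date_only], tz = "UTC", format = "%Y-%m-%d")
  ts
}

# Part-of-speech tags considered content words when a tagger is injected.
content_pos_tags <- c("NOUN", "PROPN", "VERB", "ADJ", "ADV")

#' Process a raw tweet stream
#'
#' Vectorized composition of [clean_text()], [tokenize()], [lemmatize()] and
#' [remove_stopwords()] over a stream of raw tweet records. The tweet's day
#' is the UTC calendar date of `created_at`; records with an unparseable
#' timestamp are skipped and counted (attribute `skipped`). Output order
#' follows input order.
#'
#' If a `pos_tagger` (`function(lemmas) -> tags`) is supplied, only content
#' words (`NOUN`, `PROPN`, `VERB`, `ADJ`, `ADV`) survive; the default has no
#' tagger and passes all lemmas.
#'
#' @param raws a data.frame/data.table with columns `id`, `created_at`
#'   (ISO-8601 UTC), `text`, and optionally `country_code`.
#' @param stopwords normalized stopword vector.
#' @param lemmatizer injectable lemmatizer.
#' @param pos_tagger optional part-of-speech tagger.
#' @param dedupe drop exact-duplicate texts within the same day (off by
#'   default: retweeted duplicates are kept).
#' @param keep_hashtag_word passed to [clean_text()].
#' @return a `processed_tweets` data.table with columns `id`, `day`,
#'   `country_code`, `clean_text`, `tokens` (list), `lemmas` (list,
#'   stopword-free), `topics` (list, empty until filtering assigns them).
#' @export
process_stream <- function(raws, stopwords = spanish_stopwords(),
                           lemmatizer = default_lemmatizer,
                           pos_tagger = NULL, dedupe = FALSE,
                           keep_hashtag_word = FALSE) {
  raws <- data.table::as.data.table(raws)
  need <- c("id", "created_at", "text")
  miss <- setdiff(need, names(raws))
  if (length(miss)) stop("raw stream is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!("country_code" %in% names(raws)))
    raws[, country_code := NA_character_]
  if (nrow(raws) == 0L) return(empty_processed())

  ts <- parse_utc(raws$created_at)
  ok <- !is.na(ts)
  skipped <- sum(!ok)
  if (skipped > 0L)
    message(sprintf("skipped %d tweet(s) with unparseable timestamps", skipped))
  raws <- raws[ok]
  if (nrow(raws) == 0L) {
    out <- empty_processed()
    data.table::setattr(out, "skipped", skipped)
    return(out)
  }
  day <- as.Date(ts[ok], tz = "UTC")

  if (dedupe) {
    keep <- !duplicated(data.table::data.table(day, txt = raws$text))
    raws <- raws[keep]
    day <- day[keep]
  }

  cleaned <- clean_text(raws$text, keep_hashtag_word = keep_hashtag_word)
  toks <- tokenize_many(cleaned)

  cnt <- lengths(toks)
  grp <- rep.int(seq_along(toks), cnt)
  all_lem <- lemmatizer(unlist(toks, use.names = FALSE))
  keep <- !(all_lem %in% stopwords)
  if (!is.null(pos_tagger) && length(all_lem)) {
    keep <- keep & (pos_tagger(all_lem) %in% content_pos_tags)
  }
  lems <- split(all_lem[keep], factor(grp[keep], levels = seq_along(toks)))
  lems <- unname(lems)

  out <- data.table::data.table(
    id = as.character(raws$id),
    day = day,
    country_code = toupper(as.character(raws$country_code)),
    clean_text = cleaned,
    tokens = toks,
    lemmas = lems,
    topics = rep(list(character(0)), length(toks))
  )
  data.table::setattr(out, "class",
                      c("processed_tweets", "data.table", "data.frame"))
  data.table::setattr(out, "skipped", skipped)
  out[]
}

empty_processed <- function() {
  out <- data.table::data.table(
    id = character(), day = as.Date(character()),
    country_code = character(), clean_text = character(),
    tokens = list(), lemmas = list(), topics = list()
  )
  data.table::setattr(out, "class",
                      c("processed_tweets", "data.table", "data.frame"))
  data.table::setattr(out, "skipped", 0L)
  out
}

#' Process a single raw tweet
#'
#' Convenience wrapper around [process_stream()] for one record.
#'
#' @param raw a list or one-row data.frame with `id`, `created_at`, `text`,
#'   optionally `country_code`.
#' @inheritParams process_stream
#' @return a one-row `processed_tweets` table, or `NULL` if the timestamp
#'   cannot be parsed.
#' @export
process_tweet <- function(raw, stopwords = spanish_stopwords(),
                          lemmatizer = default_lemmatizer,
                          pos_tagger = NULL) {
  df <- data.table::as.data.table(raw[c("id", "created_at", "text",
                                        intersect("country_code", names(raw)))])
  out <- process_stream(df, stopwords = stopwords, lemmatizer = lemmatizer,
                        pos_tagger = pos_tagger)
  if (nrow(out) == 0L) NULL else out
}

#' Read a tweet stream from a JSON-lines file
#'
#' One JSON object per line with keys `id`, `created_at` (ISO-8601), `text`,
#' `country_code`.
#'
#' @param path file path.
#' @return a data.table of raw tweet records.
#' @export
read_tweets_jsonl <- function(path) {
  if (!file.exists(path)) stop("tweet stream not found: ", path)
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  df <- jsonlite::stream_in(con, verbose = FALSE)
  dt <- data.table::as.data.table(df)
  if (nrow(dt) == 0L)
    dt <- data.table::data.table(id = character(), created_at = character(),
                                 text = character(), country_code = character())
  dt
}

#' Write a tweet stream to a JSON-lines file
#'
#' @param tweets a data.frame of tweet records (raw or processed).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_tweets_jsonl <- function(tweets, path) {
  df <- as.data.frame(tweets)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(df) > 0L) jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}
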