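# Three-stage keyword rule filtering (context -> topic -> country) and the
# per-country/per-topic count report.

#' Create a keyword rule set
#'
#' A named set of keyword phrases used for stream filtering. Each keyword is
#' normalized; multi-word keywords are matched as contiguous token phrases.
#'
#' @param name rule-set name (e.g. a topic).
#' @param keywords character vector of keywords/phrases (at least one).
#' @return an object of class `rule_set`.
#' @examples
#' rule_set("vaccines", c("Pfizer", "astrazeneca", "PCR"))
#' @export
rule_set <- function(name, keywords) {
  keywords <- unique(normalize_term(as.character(keywords)))
  keywords <- keywords[nzchar(keywords)]
  if (length(keywords) == 0L)
    stop("rule set '", name, "' needs at least one non-empty keyword")
  structure(
    list(name = as.character(name), keywords = keywords,
         phrases = strsplit(keywords, " +")),
    class = "rule_set"
  )
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %s: %s\n", x$name,
              paste(x$keywords, collapse = ", ")))
  invisible(x)
}

#' Does a rule set match a token sequence?
#'
#' `TRUE` iff any keyword phrase of the rule occurs as a contiguous
#' subsequence of the (normalized) tokens. Matching is at token level, not
#' substring level: the keyword `"covid"` does not match the token
#' `"covidiota"`.
#'
#' @param rule a [rule_set()].
#' @param tokens character vector of normalized tokens.
#' @return logical scalar.
#' @export
rule_matches <- function(rule, tokens) {
  stopifnot(inherits(rule, "rule_set"))
  if (length(tokens) == 0L) return(FALSE)
  plen <- lengths(rule$phrases)
  singles <- unlist(rule$phrases[plen == 1L], use.names = FALSE)
  if (length(singles) && any(tokens %in% singles)) return(TRUE)
  for (ph in rule$phrases[plen > 1L]) {
    if (phrase_in_tokens(ph, tokens)) return(TRUE)
  }
  FALSE
}

phrase_in_tokens <- function(phrase, tokens) {
  k <- length(phrase)
  n <- length(tokens)
  if (n < k) return(FALSE)
  for (s in which(tokens == phrase[1L])) {
    if (s + k - 1L <= n && all(tokens[s:(s + k - 1L)] == phrase)) return(TRUE)
  }
  FALSE
}

# Vectorized rule matching over a list of token vectors.
match_stream <- function(rule, token_list) {
  hit <- logical(length(token_list))
  if (length(token_list) == 0L) return(hit)
  plen <- lengths(rule$phrases)
  singles <- unlist(rule$phrases[plen == 1L], use.names = FALSE)
  if (length(singles)) {
    cnt <- lengths(token_list)
    grp <- rep.int(seq_along(token_list), cnt)
    toks <- unlist(token_list, use.names = FALSE)
    hit[unique(grp[toks %in% singles])] <- TRUE
  }
  multi <- rule$phrases[plen > 1L]
  if (length(multi)) {
    for (i in which(!hit)) {
      for (ph in multi) {
        if (phrase_in_tokens(ph, token_list[[i]])) { hit[i] <- TRUE; break }
      }
    }
  }
  hit
}

#' Classify a tweet into topics
#'
#' Returns the names of all topic rule sets whose keywords match; a tweet may
#' carry several topics, or none (in which case it is excluded downstream).
#'
#' @param tweet a one-row `processed_tweets` table, a list with a `tokens`
#'   field, or a plain character vector of normalized tokens.
#' @param topic_rules list of [rule_set()] objects.
#' @param match_on match against raw normalized `"tokens"` (default; keyword
#'   inflections behave as the analyst wrote them) or against `"lemmas"`.
#' @return character vector of matching topic names (possibly empty).
#' @export
classify_topics <- function(tweet, topic_rules, match_on = c("tokens", "lemmas")) {
  match_on <- match.arg(match_on)
  tokens <- if (is.character(tweet)) {
    tweet
  } else if (is.data.frame(tweet)) {
    tweet[[match_on]][[1L]]
  } else {
    tweet[[match_on]]
  }
  names_out <- unname(vapply(topic_rules, function(r) r$name, ""))
  names_out[vapply(topic_rules, rule_matches, NA, tokens = tokens)]
}

#' Filter a raw tweet stream in three stages
#'
#' Applies, in order: (1) a context rule (e.g. pandemic keywords) on the
#' normalized raw tokens; (2) topic classification, keeping tweets matching
#' at least one topic; (3) a country filter on `country_code`. Retained
#' tweets are fully processed ([process_stream()]) and carry their topic
#' set; the accompanying [counts_table] counts a tweet once per matched
#' topic, so row totals equal per-topic dataset sizes and may exceed
#' distinct-tweet counts for multi-topic tweets.
#'
#' @param raws raw tweet records (see [process_stream()]).
#' @param context a [rule_set()] for the stream context.
#' @param topics list of topic [rule_set()]s.
#' @param countries character vector of 2-letter country codes to keep.
#' @param match_on `"tokens"` (default) or `"lemmas"`.
#' @inheritParams process_stream
#' @return `list(tweets = <processed_tweets>, counts = <counts_table>)`.
#' @export
filter_stream <- function(raws, context, topics, countries,
                          stopwords = spanish_stopwords(),
                          lemmatizer = default_lemmatizer,
                          pos_tagger = NULL, dedupe = FALSE,
                          match_on = c("tokens", "lemmas")) {
  stopifnot(inherits(context, "rule_set"))
  match_on <- match.arg(match_on)
  countries <- toupper(countries)
  topic_names <- vapply(topics, function(r) r$name, "")
  proc <- process_stream(raws, stopwords = stopwords, lemmatizer = lemmatizer,
                         pos_tagger = pos_tagger, dedupe = dedupe)
  cells <- matrix(0L, nrow = length(countries), ncol = length(topic_names),
                  dimnames = list(countries, topic_names))
  if (nrow(proc) == 0L)
    return(list(tweets = proc, counts = report_counts(cells)))

  field <- proc[[match_on]]
  in_context <- match_stream(context, field)
  topic_hits <- vapply(topics, match_stream, logical(nrow(proc)),
                       token_list = field)
  if (nrow(proc) == 1L) topic_hits <- matrix(topic_hits, nrow = 1L)
  any_topic <- rowSums(topic_hits) > 0L
  in_country <- proc$country_code %in% countries
  keep <- in_context & any_topic & in_country

  retained <- proc[keep]
  hits_kept <- topic_hits[keep, , drop = FALSE]
  retained[, topics := lapply(seq_len(.N), function(i)
    topic_names[hits_kept[i, ]])]
  data.table::setattr(retained, "class",
                      c("processed_tweets", "data.table", "data.frame"))

  if (nrow(retained) > 0L) {
    for (ci in seq_along(countries)) {
      rows <- retained$country_code == countries[ci]
      if (any(rows))
        cells[ci, ] <- colSums(hits_kept[rows, , drop = FALSE])
    }
  }
  list(tweets = retained, counts = report_counts(cells))
}

#' Build a country-by-topic count report
#'
#' Computes row totals (per country), column totals (per topic) and the
#' grand total from a complete country-by-topic grid of tweet counts.
#'
#' @param cells a non-negative numeric matrix, countries in rows, topics in
#'   columns, with dimnames.
#' @return an object of class `counts_table`: `list(counts, row_totals,
#'   col_totals, grand_total)` with `row_totals[c] == sum(counts[c, ])` and
#'   `grand_total == sum(row_totals)`.
#' @examples
#' report_counts(matrix(c(1, 2, 3, 4), 2, 2,
#'                      dimnames = list(c("ES", "MX"), c("health", "economy"))))
#' @export
report_counts <- function(cells) {
  m <- as.matrix(cells)
  if (length(m) && (any(is.na(m)) || any(m < 0)))
    stop("count cells must be non-negative and complete")
  storage.mode(m) <- "double"  # totals can exceed .Machine$integer.max in principle
  structure(
    list(counts = m, row_totals = rowSums(m), col_totals = colSums(m),
         grand_total = sum(m)),
    class = "counts_table"
  )
}

#' @export
print.counts_table <- function(x, ...) {
  df <- as.data.frame(x$counts)
  df$Total <- x$row_totals
  df <- rbind(df, Total = c(x$col_totals, x$grand_total))
  print(df)
  invisible(x)
}

#' Flatten a counts table for CSV export
#'
#' @param x a `counts_table`.
#' @return a data.frame with one row per country plus a `Total` row.
#' @export
as.data.frame.counts_table <- function(x, ...) {
  df <- data.frame(country = rownames(x$counts), x$counts,
                   Total = x$row_totals, check.names = FALSE,
                   row.names = NULL)
  rbind(df, data.frame(country = "Total", t(x$col_totals),
                       Total = x$grand_total, check.names = FALSE))
}

#' Default pandemic-context rule set
#'
#' The context stage keeps tweets mentioning the pandemic at all:
#' keywords `covid`, `covid19`, `coronavirus`.
#'
#' @return a [rule_set()].
#' @export
default_context_rules <- function() {
  rule_set("context", c("covid", "covid19", "coronavirus"))
}

#' Default topic rule sets
#'
#' Five topics of interest for pandemic-period streams -- government,
#' health, economy, employment, vaccines -- each with its driving keywords
#' (normalized Spanish forms). These are configuration data, not code:
#' replace or extend them freely.
#'
#' @return named list of [rule_set()] objects.
#' @export
default_topic_rules <- function() {
  defs <- list(
    government = c("corrupcion", "gestion", "politico", "democracia"),
    health = c("depresion", "estres", "psicologo", "angustia"),
    economy = c("negocio", "empresa", "deuda", "quiebra", "pib"),
    employment = c("zoom", "skype", "videoconferencia", "desempleo", "despido"),
    vaccines = c("astrazeneca", "pfizer", "pcr", "antigenos", "eficacia")
  )
  lapply(stats::setNames(names(defs), names(defs)),
         function(nm) rule_set(nm, defs[[nm]]))
}

#' Reference corpus filtering counts
#'
#' Published tweet counts per country and topic after the three-stage
#' keyword filter (pandemic context, five topics, country availability) of a
#' 13-month Spanish-language COVID-19 Twitter corpus (March 2020 to March
#' 2021; Chile, Mexico, Peru, Spain). Used as the in-package input for count
#' arithmetic checks: feeding this grid to [report_counts()] must give row
#' totals 14759, 32713, 6916, 51109 and grand total 105497.
#'
#' @return a 4 x 5 integer matrix with country rows and topic columns.
#' @export
covid_corpus_counts <- function() {
  matrix(
    c(709, 584, 2407, 4131, 6928,
      1142, 1785, 4294, 9552, 15940,
      605, 222, 911, 1722, 3456,
      4713, 3654, 12032, 11453, 19257),
    nrow = 4, byrow = TRUE,
    dimnames = list(
      c("Chile", "Mexico", "Peru", "Spain"),
      c("government", "health", "economy", "employment", "vaccines")
    )
  )
}
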