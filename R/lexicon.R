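# Term normalization and the mutable polarity lexicon shared by the engine.

#' Normalize a term
#'
#' Lowercases, folds Spanish diacritics onto their base letters and strips
#' surrounding whitespace, so that `"Vacuna"`, `"vacuna"` and `"VACUNA"` (and
#' accented/unaccented spellings such as `"antígenos"`/`"antigenos"`) all map
#' to the same key in keyword rules and in the lexicon.
#'
#' The tilde-n (`ñ`) is deliberately preserved: folding it onto plain `n`
#' merges distinct Spanish words (e.g. "año"/"ano"). The function is
#' idempotent: `normalize_term(normalize_term(x))` equals
#' `normalize_term(x)`.
#'
#' @param text character vector of terms or free text.
#' @return character vector of the same length, normalized.
#' @examples
#' normalize_term(c("Vacuna", "antígenos", "  AÑO "))
#' @export
normalize_term <- function(text) {
  if (length(text) == 0L) return(character(0))
  x <- enc2utf8(as.character(text))
  x <- chartr(
    "ÁÉÍÓÚÜÑÀÈÌÒÙ",
    "áéíóúüñàèìòù",
    x
  )
  x <- tolower(x)
  x <- chartr(
    "áéíóúüàèìòù",
    "aeiouuaeiou",
    x
  )
  trimws(x)
}

new_lexicon <- function(dt) {
  data.table::setDT(dt)
  data.table::setcolorder(
    dt, c("lemma", "polarity", "origin", "created_on", "total_frequency")
  )
  data.table::setkeyv(dt, "lemma")
  data.table::setattr(dt, "class", c("lexicon", "data.table", "data.frame"))
  dt[]
}

#' Construct a sentiment lexicon
#'
#' A lexicon maps each (normalized, unique) lemma to a sentiment polarity in
#' \[-1, 1\], together with its provenance (`"seed"` for entries loaded from a
#' seed table, `"learned"` for entries acquired from the stream), the date a
#' learned entry was created, and a running total of the number of scored
#' tweets the word has been observed in.
#'
#' @param lemma character vector of lemmas (normalized on the way in).
#' @param polarity numeric vector of polarities in \[-1, 1\].
#' @param origin `"seed"` or `"learned"`, recycled.
#' @param created_on Date vector (NA for seed entries), recycled.
#' @param total_frequency non-negative integer vector, recycled.
#' @return an object of class `lexicon` (a keyed `data.table`).
#' @examples
#' lexicon(c("bueno", "malo"), c(0.8, -0.7))
#' @export
lexicon <- function(lemma = character(), polarity = numeric(),
                    origin = "seed", created_on = as.Date(NA),
                    total_frequency = 0L) {
  n <- length(lemma)
  lemma <- normalize_term(lemma)
  lex <- new_lexicon(data.table::data.table(
    lemma = lemma,
    polarity = as.numeric(polarity),
    origin = rep_len(as.character(origin), n),
    created_on = rep_len(as.Date(created_on), n),
    total_frequency = rep_len(as.integer(total_frequency), n)
  ))
  validate_lexicon(lex)
  lex
}

#' Validate lexicon invariants
#'
#' Checks that lemmas are unique, non-empty and self-normalized, that all
#' polarities lie in \[-1, 1\], that origins are `"seed"`/`"learned"` and that
#' every learned entry carries a creation date. Called after engine updates in
#' tests; errors on the first violation found.
#'
#' @param lex a `lexicon`.
#' @return `lex`, invisibly.
#' @export
validate_lexicon <- function(lex) {
  stopifnot(inherits(lex, "lexicon"))
  if (anyDuplicated(lex$lemma)) stop("lexicon lemmas must be unique")
  if (any(!nzchar(lex$lemma))) stop("lexicon contains an empty lemma")
  if (!identical(lex$lemma, normalize_term(lex$lemma)))
    stop("lexicon lemma is not self-normalized")
  if (any(is.na(lex$polarity)) || any(abs(lex$polarity) > 1))
    stop("lexicon polarity outside [-1, 1]")
  if (!all(lex$origin %in% c("seed", "learned")))
    stop("lexicon origin must be 'seed' or 'learned'")
  if (any(lex$origin == "learned" & is.na(lex$created_on)))
    stop("learned lexicon entry without a creation date")
  if (any(lex$total_frequency < 0L))
    stop("lexicon total_frequency must be non-negative")
  invisible(lex)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf(
    "<lexicon> %d entries (%d seed, %d learned)\n",
    nrow(x), sum(x$origin == "seed"), sum(x$origin == "learned")
  ))
  NextMethod()
}

# Named polarity vector for fast lookup in the engine hot path.
lex_polarity_vector <- function(lex) {
  stats::setNames(lex$polarity, lex$lemma)
}

#' Load a seed lexicon from a tab-separated file
#'
#' Reads a UTF-8, tab-separated table with a header line. Two layouts are
#' accepted: the two-column seed export `lemma<TAB>polarity`, and the
#' five-column layout written by [save_lexicon()] which adds `origin`,
#' `created_on` and `total_frequency`. Lemmas are normalized with
#' [normalize_term()]; when two rows collapse onto the same normalized lemma
#' the first occurrence is kept and a warning is emitted.
#'
#' @param path path to the lexicon file.
#' @return a `lexicon`.
#' @seealso [save_lexicon()]
#' @export
load_seed_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) stop("empty lexicon file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L || normalize_term(header[1L]) != "lemma")
    stop("lexicon file must start with a 'lemma<TAB>polarity' header: ", path)
  body <- fields[-1L]
  if (length(body) == 0L) {
    return(lexicon())
  }
  nf <- lengths(body)
  bad <- which(nf < 2L)
  if (length(bad))
    stop(sprintf("malformed lexicon row at line %d: expected at least 2 tab-separated fields",
                 bad[1L] + 1L))
  lemma <- normalize_term(vapply(body, `[[`, "", 1L))
  pol_chr <- vapply(body, `[[`, "", 2L)
  polarity <- suppressWarnings(as.numeric(pol_chr))
  bad <- which(is.na(polarity) | !nzchar(lemma))
  if (length(bad))
    stop(sprintf("malformed lexicon row at line %d: '%s'",
                 bad[1L] + 1L, lines[bad[1L] + 1L]))
  bad <- which(abs(polarity) > 1)
  if (length(bad))
    stop(sprintf("polarity outside [-1, 1] at line %d: '%s'",
                 bad[1L] + 1L, lines[bad[1L] + 1L]))
  if (length(header) >= 5L && all(nf >= 5L)) {
    origin <- vapply(body, `[[`, "", 3L)
    created_chr <- vapply(body, `[[`, "", 4L)
    created_on <- as.Date(ifelse(nzchar(created_chr), created_chr, NA))
    total_frequency <- as.integer(vapply(body, `[[`, "", 5L))
  } else {
    origin <- rep("seed", length(lemma))
    created_on <- rep(as.Date(NA), length(lemma))
    total_frequency <- rep(0L, length(lemma))
  }
  dup <- duplicated(lemma)
  if (any(dup)) {
    warning(sprintf(
      "%d duplicate lemma(s) after normalization; keeping first occurrence (e.g. '%s')",
      sum(dup), lemma[which(dup)[1L]]
    ))
  }
  lex <- new_lexicon(data.table::data.table(
    lemma = lemma[!dup], polarity = polarity[!dup], origin = origin[!dup],
    created_on = created_on[!dup], total_frequency = total_frequency[!dup]
  ))
  validate_lexicon(lex)
  lex
}

#' Save a lexicon to a tab-separated file
#'
#' Writes the five-column tab-separated layout (`lemma`, `polarity`,
#' `origin`, `created_on`, `total_frequency`), UTF-8, one header line.
#' Polarities are written with six decimal places; `load_seed_lexicon()`
#' applied to the output reproduces all lemmas, origins and polarities to
#' that precision.
#'
#' @param lex a `lexicon`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
save_lexicon <- function(lex, path) {
  validate_lexicon(lex)
  out <- data.table::data.table(
    lemma = lex$lemma,
    polarity = sprintf("%.6f", lex$polarity),
    origin = lex$origin,
    created_on = ifelse(is.na(lex$created_on), "",
                        format(lex$created_on, "%Y-%m-%d")),
    total_frequency = lex$total_frequency
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}
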