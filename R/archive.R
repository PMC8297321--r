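# Append-only archive of per-word daily sentiment history, with query and
# CSV round-trip.

archive_cols <- c("country", "lemma", "day", "polarity_after",
                  "daily_mean", "daily_count")

new_archive <- function(dt) {
  data.table::setDT(dt)
  data.table::setcolorder(dt, archive_cols)
  data.table::setattr(dt, "class",
                      c("sentiment_archive", "data.table", "data.frame"))
  dt[]
}

#' Construct a sentiment archive
#'
#' The archive stores the historical per-word sentiment trace: one record
#' per `(country, lemma, day)` with the polarity after that day's update
#' (`polarity_after`), the day's mean evidence (`daily_mean`) and the number
#' of defined-score tweets containing the word (`daily_count`). It is the
#' faithful trace of the engine: replaying the update recursion from the
#' seed lexicon over the stored evidence reproduces every stored polarity.
#'
#' @param records optional data.frame with columns `lemma`, `day`,
#'   `polarity_after`, `daily_mean`, `daily_count` and optionally `country`
#'   (default `"all"`).
#' @return a `sentiment_archive`.
#' @export
sentiment_archive <- function(records = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    return(new_archive(data.table::data.table(
      country = character(), lemma = character(), day = as.Date(character()),
      polarity_after = numeric(), daily_mean = numeric(),
      daily_count = integer()
    )))
  }
  dt <- data.table::as.data.table(records)
  if (!("country" %in% names(dt))) dt[, country := "all"]
  arch <- new_archive(dt)
  validate_archive(arch)
  arch
}

validate_archive <- function(arch) {
  stopifnot(inherits(arch, "sentiment_archive"))
  miss <- setdiff(archive_cols, names(arch))
  if (length(miss)) stop("archive is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(arch) == 0L) return(invisible(arch))
  if (any(is.na(arch$day))) stop("archive contains unparseable days")
  if (any(abs(arch$polarity_after) > 1) || any(abs(arch$daily_mean) > 1))
    stop("archive polarity outside [-1, 1]")
  if (any(arch$daily_count < 1L)) stop("archive daily_count must be >= 1")
  key <- paste(arch$country, arch$lemma, arch$day)
  if (anyDuplicated(key))
    stop("duplicate archive key: ", key[anyDuplicated(key)])
  invisible(arch)
}

#' Append records to an archive
#'
#' @param archive a [sentiment_archive()].
#' @param records a data.frame of new records (same columns). Appending a
#'   record whose `(country, lemma, day)` key is already present is an
#'   error.
#' @return the extended archive.
#' @export
archive_append <- function(archive, records) {
  stopifnot(inherits(archive, "sentiment_archive"))
  add <- sentiment_archive(records)
  if (nrow(add) == 0L) return(archive)
  out <- new_archive(rbind(data.table::as.data.table(archive),
                           data.table::as.data.table(add)))
  validate_archive(out)
  out
}

#' Extract a word's sentiment series
#'
#' @param archive a [sentiment_archive()].
#' @param lemma the word (normalized on the way in).
#' @param country country code or `"all"`.
#' @param from,to optional inclusive date bounds.
#' @return a data.table `(day, polarity_after)` in chronological order;
#'   zero rows if the word has no records in range.
#' @export
get_series <- function(archive, lemma, country = "all",
                       from = NULL, to = NULL) {
  stopifnot(inherits(archive, "sentiment_archive"))
  w <- normalize_term(lemma)
  cc <- country
  out <- archive[archive$lemma == w & archive$country == cc,
                 list(day, polarity_after)]
  if (!is.null(from)) out <- out[day >= as.Date(from)]
  if (!is.null(to)) out <- out[day <= as.Date(to)]
  data.table::setorder(out, day)
  out[]
}

#' Export an archive to CSV
#'
#' Columns `country, lemma, day, polarity_after, daily_mean, daily_count`,
#' days in ISO-8601. [import_archive_csv()] on the output reproduces all
#' fields (polarities to at least six decimal places).
#'
#' @param archive a [sentiment_archive()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
export_archive_csv <- function(archive, path) {
  stopifnot(inherits(archive, "sentiment_archive"))
  out <- data.table::as.data.table(archive)
  data.table::fwrite(out, path, dateTimeAs = "ISO")
  invisible(path)
}

#' Import an archive from CSV
#'
#' @param path a CSV written by [export_archive_csv()].
#' @return a [sentiment_archive()].
#' @export
import_archive_csv <- function(path) {
  if (!file.exists(path)) stop("archive file not found: ", path)
  dt <- tryCatch(
    # fread warns about colClasses on truncated files; the structural
    # validation below raises the meaningful error
    suppressWarnings(data.table::fread(path, colClasses = list(
      character = c("country", "lemma", "day"),
      numeric = c("polarity_after", "daily_mean"),
      integer = "daily_count"
    ))),
    error = function(e) stop("malformed archive file: ", conditionMessage(e),
                             call. = FALSE)
  )
  miss <- setdiff(archive_cols, names(dt))
  if (length(miss))
    stop("malformed archive file: missing column(s) ",
         paste(miss, collapse = ", "))
  day_parsed <- as.Date(dt$day, format = "%Y-%m-%d")
  bad <- which(is.na(day_parsed) | is.na(dt$polarity_after) |
                 is.na(dt$daily_count))
  if (length(bad))
    stop(sprintf("malformed archive row at line %d", bad[1L] + 1L))
  data.table::set(dt, j = "day", value = day_parsed)
  sentiment_archive(dt)
}
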