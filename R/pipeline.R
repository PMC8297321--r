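# Orchestration: configuration validation, the end-to-end pipeline run, and
# a small command-line front end.

#' Validate a pipeline configuration
#'
#' Reads a JSON configuration file, applies defaults, and either returns a
#' fully resolved `pipeline_config` or fails with *all* validation errors
#' collected (not just the first). Recognised keys:
#'
#' * `input` (path, JSON-lines tweet stream) and `lexicon` (path, seed TSV)
#'   -- required, must exist;
#' * `output_dir` -- required;
#' * `stopwords`, `extra_stopwords` (paths or inline array) -- optional;
#' * `rules`: `context` (array), `topics` (object name -> array),
#'   `countries` (array) -- optional, defaulting to the bundled rules and
#'   the four reference countries;
#' * `engine`: `alpha`, `min_learn_occurrences`, `learn_enabled`;
#' * `dates`: `from`, `to` (ISO dates, well-ordered);
#' * `viz`: `words` (array), `window_days` (integer, default 30);
#' * `seed` (integer, default 1).
#'
#' @param path path to the JSON config file, or an already-parsed list.
#' @return a `pipeline_config` list.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    path
  }
  errs <- character()
  err <- function(...) errs <<- c(errs, sprintf(...))

  for (key in c("input", "lexicon", "output_dir")) {
    if (is.null(raw[[key]])) err("missing required key '%s'", key)
  }
  for (key in c("input", "lexicon")) {
    p <- raw[[key]]
    if (!is.null(p) && !file.exists(p)) err("%s: file not found '%s'", key, p)
  }
  if (!is.null(raw$stopwords) && !file.exists(raw$stopwords))
    err("stopwords: file not found '%s'", raw$stopwords)

  eng <- raw$engine
  alpha <- eng$alpha %||% 0.3
  min_learn <- eng$min_learn_occurrences %||% 5L
  learn <- eng$learn_enabled %||% TRUE
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    err("engine.alpha must be in (0, 1], got %s", deparse(alpha))
  if (!is.numeric(min_learn) || min_learn < 1)
    err("engine.min_learn_occurrences must be a positive integer")

  from <- to <- NULL
  if (!is.null(raw$dates)) {
    from <- tryCatch(as.Date(raw$dates$from), error = function(e) NA)
    to <- tryCatch(as.Date(raw$dates$to), error = function(e) NA)
    if (!is.null(raw$dates$from) && is.na(from))
      err("dates.from is not a valid date: '%s'", raw$dates$from)
    if (!is.null(raw$dates$to) && is.na(to))
      err("dates.to is not a valid date: '%s'", raw$dates$to)
    if (!is.null(from) && !is.null(to) && !is.na(from) && !is.na(to) &&
        from > to)
      err("date range is not well-ordered: %s > %s", from, to)
  }

  topics_raw <- raw$rules$topics
  topics <- if (is.null(topics_raw)) default_topic_rules() else {
    if (!length(names(topics_raw))) {
      err("rules.topics must be a named object of keyword arrays")
      list()
    } else {
      lapply(stats::setNames(names(topics_raw), names(topics_raw)),
             function(nm) rule_set(nm, topics_raw[[nm]]))
    }
  }
  context <- if (is.null(raw$rules$context)) default_context_rules() else
    rule_set("context", raw$rules$context)
  countries <- toupper(raw$rules$countries %||% c("CL", "MX", "PE", "ES"))

  if (length(errs))
    stop("config validation failed:\n- ", paste(errs, collapse = "\n- "),
         call. = FALSE)

  structure(list(
    input = raw$input, lexicon = raw$lexicon, output_dir = raw$output_dir,
    stopwords_path = raw$stopwords,
    extra_stopwords = normalize_term(raw$extra_stopwords %||% character()),
    context = context, topics = topics, countries = countries,
    engine = engine_config(alpha, min_learn, learn),
    from = from, to = to,
    viz_words = raw$viz$words %||% NULL,
    viz_window_days = as.integer(raw$viz$window_days %||% 30L),
    seed = as.integer(raw$seed %||% 1L)
  ), class = "pipeline_config")
}

run_stage <- function(name, expr, quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  if (!quiet)
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full pipeline and write all artifacts
#'
#' Executes filter -> engine (one run per country plus a pooled `"all"`
#' run) -> trend extraction -> snapshot -> frequency cloud -> report, and
#' writes every artifact under `cfg$output_dir`:
#' `retained.jsonl`, `counts.csv`, `archive.csv`, `lexicon_final.tsv` (pooled)
#' and `lexicon_<CC>.tsv` per country, `trends.csv` (+ `trends.png`),
#' `snapshot.json` (+ `cloud.png`), `freqcloud.csv` (+ `freqcloud.png`) and
#' `manifest.json` (config hash, seed, record counts). With identical config
#' and input, all CSV/JSON artifacts are byte-identical across runs; images
#' are excluded from that guarantee.
#'
#' @param cfg a `pipeline_config` (or the path to a JSON config, which is
#'   validated first).
#' @param quiet suppress per-stage timing messages.
#' @param stages subset of stages whose artifacts should be written
#'   (upstream stages always run).
#' @return the manifest list, invisibly.
#' @export
run_all <- function(cfg, quiet = FALSE,
                    stages = c("filter", "run", "trends", "cloud",
                               "freqcloud", "report")) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(cfg$output_dir, f)

  lex <- run_stage("load", load_seed_lexicon(cfg$lexicon), quiet)
  base_sw <- if (is.null(cfg$stopwords_path)) spanish_stopwords() else
    load_stopwords(cfg$stopwords_path)
  sw <- unique(c(base_sw, cfg$extra_stopwords))
  raws <- run_stage("read", read_tweets_jsonl(cfg$input), quiet)
  n_input <- nrow(raws)

  fl <- run_stage("filter", {
    res <- filter_stream(raws, cfg$context, cfg$topics, cfg$countries,
                         stopwords = sw)
    tw <- res$tweets
    if (!is.null(cfg$from)) tw <- tw[tw$day >= cfg$from]
    if (!is.null(cfg$to)) tw <- tw[tw$day <= cfg$to]
    list(tweets = tw, counts = res$counts)
  }, quiet)
  retained <- fl$tweets

  if ("filter" %in% stages) {
    rt <- data.table::as.data.table(retained)
    rt <- rt[, list(id, day = format(day), country_code, clean_text,
                    lemmas, topics)]
    write_tweets_jsonl(rt, outp("retained.jsonl"))
    utils::write.csv(as.data.frame(fl$counts), outp("counts.csv"),
                     row.names = FALSE)
  }

  pooled <- run_stage("run",
                      run_stream(retained, lex, cfg$engine, country = "all"),
                      quiet)
  arch_parts <- list(data.table::as.data.table(pooled$archive))
  for (cc in cfg$countries) {
    sub <- retained[retained$country_code == cc]
    if (nrow(sub) == 0L) next
    res <- run_stream(sub, lex, cfg$engine, country = cc)
    arch_parts[[length(arch_parts) + 1L]] <-
      data.table::as.data.table(res$archive)
    if ("run" %in% stages)
      save_lexicon(res$lexicon, outp(sprintf("lexicon_%s.tsv", cc)))
  }
  archive <- sentiment_archive(data.table::rbindlist(arch_parts))
  if ("run" %in% stages) {
    export_archive_csv(archive, outp("archive.csv"))
    save_lexicon(pooled$lexicon, outp("lexicon_final.tsv"))
  }

  viz_words <- cfg$viz_words %||%
    utils::head(frequency_cloud(retained)$lemma, 8L)

  if ("trends" %in% stages && length(viz_words)) {
    ser <- plot_trends(archive, viz_words, countries = "all",
                       file = outp("trends.png"))
    data.table::fwrite(ser, outp("trends.csv"), dateTimeAs = "ISO")
  }

  if ("cloud" %in% stages && nrow(archive) > 0L && length(viz_words) >= 2L) {
    to <- max(archive$day)
    from <- to - cfg$viz_window_days + 1L
    snap <- tryCatch(
      cloud_snapshot(archive, retained, viz_words, from, to),
      error = function(e) {
        message("snapshot skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(snap)) {
      jsonlite::write_json(
        list(window = list(from = format(snap$from), to = format(snap$to)),
             country = snap$country,
             words = as.data.frame(snap$words)),
        outp("snapshot.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      plot_cloud(snap, file = outp("cloud.png"))
    }
  }

  if ("freqcloud" %in% stages) {
    fc <- frequency_cloud(retained, extra_stopwords = cfg$extra_stopwords)
    data.table::fwrite(fc, outp("freqcloud.csv"))
    plot_frequency_cloud(fc, file = outp("freqcloud.png"))
  }

  manifest <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    n_input = n_input,
    n_retained = nrow(retained),
    counts_grand_total = fl$counts$grand_total,
    n_archive_records = nrow(archive),
    countries = cfg$countries,
    outputs = sort(list.files(cfg$output_dir))
  )
  if ("report" %in% stages)
    jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_hash <- function(cfg) {
  plain <- cfg
  plain$context <- plain$context$keywords
  plain$topics <- lapply(plain$topics, function(r) r$keywords)
  plain$engine <- unclass(plain$engine)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  opts
}

cli_usage <- function() {
  cat(
    "usage: sentidrift <command> [--config PATH] [options]\n",
    "commands:\n",
    "  synth     --out DIR [--seed N]      generate a synthetic stream\n",
    "                                      (stream.jsonl, truth.csv, lexicon.tsv)\n",
    "  filter    --config PATH             filter stage artifacts\n",
    "  run       --config PATH             engine stage artifacts\n",
    "  trends    --config PATH             trend series + plot\n",
    "  cloud     --config PATH             similarity word-cloud snapshot\n",
    "  freqcloud --config PATH             frequency cloud\n",
    "  report    --config PATH             counts + manifest\n",
    "  all       --config PATH             everything\n",
    sep = ""
  )
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`synth`, `filter`, `run`, `trends`,
#' `cloud`, `freqcloud`, `report`, `all`). Installed alongside the package
#' as the `inst/cli/sentidrift` Rscript wrapper.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return exit status, invisibly (0 on success).
#' @export
sentidrift_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cli_usage()
    return(invisible(1L))
  }
  cmd <- args[1L]
  opts <- parse_cli_opts(args[-1L])

  if (cmd == "synth") {
    out <- opts$out %||% "."
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    cfg <- if (!is.null(opts$config)) {
      synth_config_from_json(opts$config)
    } else if (!is.null(opts$seed)) {
      synth_config(seed = as.integer(opts$seed))
    } else {
      default_recovery_scenario()
    }
    lex <- scenario_lexicon(cfg)
    gen <- generate_stream(cfg, lex)
    write_tweets_jsonl(gen$tweets, file.path(out, "stream.jsonl"))
    data.table::fwrite(gen$truth, file.path(out, "truth.csv"),
                       dateTimeAs = "ISO")
    save_lexicon(lex, file.path(out, "lexicon.tsv"))
    message(sprintf("wrote %d tweets to %s", nrow(gen$tweets), out))
    return(invisible(0L))
  }

  stage_map <- list(
    filter = "filter", run = c("filter", "run"),
    trends = c("filter", "run", "trends"),
    cloud = c("filter", "run", "cloud"),
    freqcloud = c("filter", "freqcloud"),
    report = c("filter", "run", "report"),
    all = c("filter", "run", "trends", "cloud", "freqcloud", "report")
  )
  if (!(cmd %in% names(stage_map))) {
    cli_usage()
    return(invisible(1L))
  }
  if (is.null(opts$config)) {
    message("missing --config PATH")
    return(invisible(1L))
  }
  cfg <- validate_config(opts$config)
  if (!is.null(opts$alpha))
    cfg$engine <- engine_config(as.numeric(opts$alpha),
                                cfg$engine$min_learn_occurrences,
                                cfg$engine$learn_enabled)
  if (!is.null(opts$lexicon)) cfg$lexicon <- opts$lexicon
  run_all(cfg, stages = stage_map[[cmd]])
  invisible(0L)
}
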