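#' Daily post-count series with peak detection
#'
#' Counts posts per calendar day (UTC by default, half-open day
#' intervals), including zero-count days inside the observed range, and
#' flags peaks: interior days strictly exceeding both neighbours by at
#' least `prominence`.
#'
#' @param posts Data frame with a `timestamp` column (ISO-8601 strings).
#' @param prominence Minimum excess over the larger neighbour for a day
#'   to count as a peak (default 0, i.e. any strict local maximum).
#' @param tz Time zone for day binning (default `"UTC"`).
#' @return Object of class `daily_series`: `series` (tibble `date`, `n`,
#'   `is_peak`) and `peaks` (Date vector).
#' @export
daily_counts <- function(posts, prominence = 0, tz = "UTC") {
  ts <- as.character(posts$timestamp)
  if (length(ts) == 0) {
    series <- tibble::tibble(date = as.Date(character()), n = integer(),
                             is_peak = logical())
    return(structure(list(series = series, peaks = as.Date(character())),
                     class = "daily_series"))
  }
  formats <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
               "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  parsed <- as.POSIXct(rep(NA_real_, length(ts)), tz = tz,
                       origin = "1970-01-01")
  for (fmt in formats) {
    miss <- is.na(parsed)
    if (!any(miss)) break
    parsed[miss] <- as.POSIXct(strptime(ts[miss], fmt, tz = tz))
  }
  bad <- which(is.na(parsed))
  if (length(bad) > 0) {
    ids <- if (!is.null(posts$post_id)) posts$post_id[bad] else bad
    stop("unparseable timestamp for post(s): ",
         paste(utils::head(ids, 5), collapse = ", "), call. = FALSE)
  }
  day <- as.Date(parsed, tz = tz)
  full <- seq(min(day), max(day), by = "day")
  n <- as.integer(table(factor(as.character(day),
                               levels = as.character(full))))
  is_peak <- rep(FALSE, length(full))
  if (length(full) >= 3) {
    for (i in 2:(length(full) - 1)) {
      nb <- max(n[i - 1], n[i + 1])
      is_peak[i] <- n[i] > nb && (n[i] - nb) >= prominence
    }
  }
  series <- tibble::tibble(date = full, n = n, is_peak = is_peak)
  structure(list(series = series, peaks = full[is_peak]),
            class = "daily_series")
}

#' Assemble a pipeline run configuration
#'
#' Inputs may be given as file paths (loaded with the package readers)
#' or as in-memory objects. Precedence and defaults follow the
#' documented arguments; the configuration is echoed into the run
#' manifest.
#'
#' @param corpus Corpus path (JSONL/CSV) or tibble with `post_id`,
#'   `timestamp`, `text`.
#' @param lexicon Lexicon path (TSV) or [emotion_lexicon()].
#' @param out_dir Output run directory (created; must not exist or be
#'   empty).
#' @param stopwords Optional stop-word path or [stopword_list()].
#' @param user_dict Optional extra tokenizer dictionary words.
#' @param min_chars Validity filter threshold (default 10).
#' @param filter_on_cleaned Count cleaned characters in the filter.
#' @param weighting,use_aux,include_neutral Sentiment options, see
#'   [match_emotions()] and [corpus_proportions()].
#' @param k_range Topic counts to sweep (default `1:8`).
#' @param lda_alpha,lda_beta,iterations,burn_in LDA options; `NULL`
#'   `lda_alpha` means the per-K default `50 / K`.
#' @param topN Keywords per emotion/topic table.
#' @param seed Integer seed controlling every stochastic stage.
#' @param gold Optional gold-label path (CSV `post_id`, `label`) or
#'   tibble, enabling the evaluation stage.
#' @param thresholds Validity thresholds for [validity_gate()].
#' @param averaging `"macro"` or `"micro"` for [prf_multiclass()].
#' @return List of class `run_config`.
#' @export
run_config <- function(corpus, lexicon, out_dir, stopwords = NULL,
                       user_dict = NULL, min_chars = 10L,
                       filter_on_cleaned = TRUE,
                       weighting = c("intensity", "count"), use_aux = TRUE,
                       include_neutral = FALSE, k_range = 1:8,
                       lda_alpha = NULL, lda_beta = 0.01,
                       iterations = 500L, burn_in = 100L, topN = 10L,
                       seed = 42L, gold = NULL,
                       thresholds = list(accuracy = 0.85, recall = 0.80,
                                         f1 = 0.80),
                       averaging = c("macro", "micro")) {
  weighting <- match.arg(weighting)
  averaging <- match.arg(averaging)
  for (p in list(corpus, lexicon, stopwords, gold)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  structure(
    list(corpus = corpus, lexicon = lexicon, out_dir = out_dir,
         stopwords = stopwords, user_dict = user_dict,
         min_chars = as.integer(min_chars),
         filter_on_cleaned = filter_on_cleaned, weighting = weighting,
         use_aux = use_aux, include_neutral = include_neutral,
         k_range = as.integer(k_range), lda_alpha = lda_alpha,
         lda_beta = lda_beta, iterations = as.integer(iterations),
         burn_in = as.integer(burn_in), topN = as.integer(topN),
         seed = as.integer(seed), gold = gold, thresholds = thresholds,
         averaging = averaging),
    class = "run_config"
  )
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

write_csv_file <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Executes clean -> length filter -> segmentation -> stop-word removal
#' -> emotion classification -> corpus proportions and per-emotion
#' keyword tables -> bag-of-words -> LDA K-sweep with perplexity and
#' coherence -> topic selection and summaries -> daily post-count series
#' (and, when gold labels are configured, kappa/precision-recall-F1
#' evaluation). All stage outputs plus a manifest with record-count
#' bookkeeping are written under the run directory; re-running the same
#' configuration reproduces every output byte-for-byte apart from the
#' manifest's wall-clock field. A stage failure leaves a `FAILED` marker
#' naming the stage, with earlier outputs retained.
#'
#' Run directory layout: `manifest.json`, `cleaned.jsonl`,
#' `profiles.jsonl`, `summary.json`, `keywords/<emotion>.csv`,
#' `ksweep.csv`, `topics/topic_<k>.csv`, `topics/intensity.csv`,
#' `daily_counts.csv`, `evaluation/*.json`.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "keywords"), showWarnings = FALSE)
  dir.create(file.path(out, "topics"), showWarnings = FALSE)
  stage <- "load"
  on_fail <- function(e) {
    writeLines(c(stage, conditionMessage(e)), file.path(out, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    posts <- if (is.character(config$corpus)) {
      read_corpus(config$corpus)
    } else {
      tibble::as_tibble(config$corpus)
    }
    lexicon <- if (is.character(config$lexicon)) {
      load_lexicon(config$lexicon)
    } else {
      config$lexicon
    }
    stopwords <- if (is.character(config$stopwords)) {
      load_stopwords(config$stopwords)
    } else {
      config$stopwords
    }

    stage <- "preprocess"
    prep <- preprocess_corpus(posts, lexicon, stopwords = stopwords,
                              user_dict = config$user_dict,
                              min_chars = config$min_chars,
                              on_cleaned = config$filter_on_cleaned)
    docs <- prep$docs
    write_tokenized(docs, file.path(out, "cleaned.jsonl"))

    stage <- "classify"
    profiles <- classify_corpus(docs, lexicon, use_aux = config$use_aux,
                                weighting = config$weighting)
    write_profiles(profiles, file.path(out, "profiles.jsonl"))
    summary <- corpus_proportions(profiles,
                                  include_neutral = config$include_neutral)
    if (summary$degenerate) {
      warning("pipeline: corpus classified no documents at all")
    }
    write_json_file(
      list(proportions = as.list(summary$proportions),
           n_classified = summary$n_classified,
           n_neutral = summary$n_neutral,
           degenerate = summary$degenerate),
      file.path(out, "summary.json")
    )

    stage <- "keywords"
    for (emo in emotion_categories()) {
      kw <- top_keywords(docs, lexicon, emo, k = config$topN)
      write_csv_file(kw, file.path(out, "keywords",
                                   paste0(tolower(emo), ".csv")))
    }

    stage <- "topics"
    bow <- make_bow(docs)
    topic_block <- NULL
    if (bow$M > 0 && sum(bow$N_d) > 0 && bow$V > 0) {
      sweep <- sweep_k(bow, config$k_range, alpha = config$lda_alpha,
                       beta = config$lda_beta,
                       iterations = config$iterations,
                       burn_in = config$burn_in, seed = config$seed,
                       topN = config$topN)
      write_csv_file(sweep$records, file.path(out, "ksweep.csv"))
      best <- fit_lda(bow, sweep$selected_K,
                      alpha = if (is.null(config$lda_alpha))
                        50 / sweep$selected_K else config$lda_alpha,
                      beta = config$lda_beta,
                      iterations = config$iterations,
                      burn_in = config$burn_in,
                      seed = config$seed + sweep$selected_K)
      topics <- summarize_topics(best, topN = config$topN)
      for (k in seq_len(best$K)) {
        write_csv_file(topics$topics[[k]],
                       file.path(out, "topics", sprintf("topic_%02d.csv", k)))
      }
      write_csv_file(
        tibble::tibble(topic = seq_len(best$K),
                       intensity = topics$intensity),
        file.path(out, "topics", "intensity.csv")
      )
      topic_block <- list(selected_K = sweep$selected_K,
                          k_range = range(config$k_range))
    } else {
      write_csv_file(tibble::tibble(K = integer(), perplexity = numeric(),
                                    log_perplexity = numeric(),
                                    coherence = numeric()),
                     file.path(out, "ksweep.csv"))
    }

    stage <- "daily_series"
    ds <- daily_counts(docs)
    write_csv_file(ds$series, file.path(out, "daily_counts.csv"))

    stage <- "evaluation"
    eval_block <- NULL
    if (!is.null(config$gold)) {
      dir.create(file.path(out, "evaluation"), showWarnings = FALSE)
      gold <- if (is.character(config$gold)) {
        utils::read.csv(config$gold, colClasses = "character",
                        fileEncoding = "UTF-8")
      } else {
        as.data.frame(config$gold)
      }
      shared <- intersect(gold$post_id, profiles$post_id)
      ref <- gold$label[match(shared, gold$post_id)]
      pred <- profiles$dominant[match(shared, profiles$post_id)]
      vr <- prf_multiclass(ref, pred, averaging = config$averaging)
      gate <- validity_gate(vr, thresholds = config$thresholds)
      ar <- cohen_kappa(ref, pred)
      write_json_file(
        list(accuracy = vr$accuracy, precision = vr$precision,
             recall = vr$recall, f1 = vr$f1, averaging = vr$averaging,
             gate = as.list(gate)),
        file.path(out, "evaluation", "validity.json")
      )
      write_json_file(
        list(kappa = ar$kappa, band = ar$band, po = ar$po, pe = ar$pe,
             n = ar$n),
        file.path(out, "evaluation", "agreement.json")
      )
      eval_block <- list(n_evaluated = length(shared))
    }

    stage <- "manifest"
    cfg_echo <- config
    cfg_echo$corpus <- if (is.character(config$corpus)) config$corpus else "<in-memory>"
    cfg_echo$lexicon <- if (is.character(config$lexicon)) config$lexicon else "<in-memory>"
    cfg_echo$stopwords <- if (is.character(config$stopwords)) config$stopwords else if (is.null(config$stopwords)) NULL else "<in-memory>"
    cfg_echo$gold <- if (is.character(config$gold)) config$gold else if (is.null(config$gold)) NULL else "<in-memory>"
    cfg_json <- jsonlite::toJSON(unclass(cfg_echo), auto_unbox = TRUE,
                                 digits = NA, null = "null")
    tmp <- tempfile()
    writeLines(cfg_json, tmp)
    cfg_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
    manifest <- list(
      package = "emotopic",
      version = as.character(utils::packageVersion("emotopic")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      seed = config$seed,
      config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
      config_hash = cfg_hash,
      counts = c(
        list(
          n_input = nrow(posts),
          n_retained = nrow(docs),
          n_dropped = prep$dropped_count,
          n_classified = summary$n_classified,
          n_neutral = summary$n_neutral,
          vocabulary_size = bow$V
        ),
        topic_block, eval_block
      )
    )
    write_json_file(manifest, file.path(out, "manifest.json"))
    invisible(out)
  }, error = on_fail)
}

write_profiles <- function(profiles, path) {
  cats <- emotion_categories()
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(profiles))) {
    counts <- as.list(setNames(
      as.integer(unlist(profiles[i, paste0("count_", cats)])), cats))
    scores <- as.list(setNames(
      as.numeric(unlist(profiles[i, paste0("score_", cats)])), cats))
    writeLines(jsonlite::toJSON(
      list(post_id = profiles$post_id[i], dominant = profiles$dominant[i],
           counts = counts, scores = scores),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
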