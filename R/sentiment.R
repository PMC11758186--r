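#' Match a tokenized document against the affect lexicon
#'
#' Every token occurrence is looked up in the lexicon; each hit
#' contributes its primary attribution and, when `use_aux = TRUE` and the
#' word carries one, its auxiliary attribution. Per category the profile
#' records a match count and a score: the sum of attributed intensities
#' (`weighting = "intensity"`, default) or the plain count
#' (`weighting = "count"`). The dominant emotion is the score argmax,
#' with exact ties broken by the canonical category order
#' ([emotion_categories()]); a document with no matches at all is
#' `"none"` (neutral).
#'
#' @param doc Either a character vector of tokens or a list/row with
#'   fields `post_id` and `tokens`.
#' @param lexicon An [emotion_lexicon()].
#' @param use_aux Count auxiliary-emotion attributions (default TRUE).
#' @param weighting `"intensity"` or `"count"`.
#' @return List of class `emotion_profile`: `post_id`, `counts` (named
#'   integer, 7 categories), `scores` (named numeric), `dominant`.
#' @export
match_emotions <- function(doc, lexicon, use_aux = TRUE,
                           weighting = c("intensity", "count")) {
  weighting <- match.arg(weighting)
  if (is.character(doc)) {
    tokens <- doc
    post_id <- NA_character_
  } else {
    tokens <- doc$tokens
    if (is.list(tokens)) tokens <- tokens[[1]]
    post_id <- as.character(doc$post_id %||% NA_character_)
  }
  cats <- emotion_categories()
  counts <- setNames(integer(7), cats)
  iscore <- setNames(numeric(7), cats)
  e <- lexicon$entries
  idx <- match(tokens, e$word)
  idx <- idx[!is.na(idx)]
  if (length(idx) > 0) {
    for (i in idx) {
      em <- e$emotion[i]
      counts[em] <- counts[em] + 1L
      iscore[em] <- iscore[em] + e$intensity[i]
      if (use_aux && !is.na(e$aux_emotion[i])) {
        am <- e$aux_emotion[i]
        counts[am] <- counts[am] + 1L
        iscore[am] <- iscore[am] + e$aux_intensity[i]
      }
    }
  }
  scores <- if (weighting == "intensity") iscore else as.numeric(counts)
  dominant <- if (sum(counts) == 0L) {
    "none"
  } else {
    cats[which.max(scores)] # which.max takes the first max: canonical order
  }
  structure(
    list(post_id = post_id, counts = counts, scores = scores,
         dominant = dominant),
    class = "emotion_profile"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify every document of a corpus
#'
#' Batch application of [match_emotions()]; one profile row per document,
#' order preserved, fully deterministic.
#'
#' @param docs Tibble with `post_id` and a `tokens` list-column (as
#'   produced by [preprocess_corpus()]), or a plain list of token
#'   vectors.
#' @param lexicon An [emotion_lexicon()].
#' @inheritParams match_emotions
#' @return Tibble with columns `post_id`, `dominant`, then
#'   `count_<category>` and `score_<category>` for the 7 categories.
#' @export
classify_corpus <- function(docs, lexicon, use_aux = TRUE,
                            weighting = c("intensity", "count")) {
  weighting <- match.arg(weighting)
  cats <- emotion_categories()
  if (is.data.frame(docs)) {
    ids <- as.character(docs$post_id)
    toks <- docs$tokens
  } else {
    toks <- docs
    ids <- names(docs) %||% as.character(seq_along(docs))
  }
  n <- length(toks)
  counts <- matrix(0L, n, 7, dimnames = list(NULL, cats))
  scores <- matrix(0, n, 7, dimnames = list(NULL, cats))
  dominant <- character(n)
  for (i in seq_len(n)) {
    p <- match_emotions(toks[[i]], lexicon, use_aux = use_aux,
                        weighting = weighting)
    counts[i, ] <- p$counts
    scores[i, ] <- p$scores
    dominant[i] <- p$dominant
  }
  out <- tibble::tibble(post_id = ids, dominant = dominant)
  for (c in cats) out[[paste0("count_", c)]] <- counts[, c]
  for (c in cats) out[[paste0("score_", c)]] <- scores[, c]
  out
}

#' Corpus-level emotion proportions
#'
#' Shares of documents per dominant emotion. By default neutral documents
#' (dominant `"none"`) are excluded from the denominator, matching the
#' convention of reporting seven proportions that sum to 100%; their
#' number is reported separately. With `include_neutral = TRUE` an eighth
#' `none` share is included.
#'
#' @param profiles Tibble from [classify_corpus()] (needs a `dominant`
#'   column), or a character vector of dominant labels.
#' @param include_neutral Include a `none` share (default FALSE).
#' @return List of class `corpus_emotion_summary`: `proportions` (named
#'   numeric summing to 1 when any document is classified),
#'   `n_classified`, `n_neutral`, and `degenerate` (TRUE when no document
#'   at all was classified, in which case proportions are all zero and a
#'   warning is emitted).
#' @export
corpus_proportions <- function(profiles, include_neutral = FALSE) {
  dominant <- if (is.character(profiles)) profiles else profiles$dominant
  cats <- emotion_categories()
  n_neutral <- sum(dominant == "none")
  n_classified <- sum(dominant != "none")
  levels <- if (include_neutral) c(cats, "none") else cats
  denom <- if (include_neutral) length(dominant) else n_classified
  counts <- table(factor(dominant[dominant %in% levels], levels = levels))
  degenerate <- denom == 0
  props <- if (degenerate) {
    if (length(dominant) > 0) {
      warning("no classified documents; proportions reported as all zero")
    }
    setNames(numeric(length(levels)), levels)
  } else {
    setNames(as.numeric(counts) / denom, levels)
  }
  structure(
    list(proportions = props, n_classified = n_classified,
         n_neutral = n_neutral, degenerate = degenerate),
    class = "corpus_emotion_summary"
  )
}

#' @export
print.corpus_emotion_summary <- function(x, ...) {
  cat(sprintf("<corpus_emotion_summary> %d classified, %d neutral\n",
              x$n_classified, x$n_neutral))
  print(round(x$proportions, 4))
  invisible(x)
}

#' Top keywords of an emotion category
#'
#' The `k` lexicon words whose primary category is `emotion` with the
#' highest total occurrence frequency across the corpus, each reported
#' with its part-of-speech class and intensity (the layout of a
#' per-emotion keyword table). Ties are broken lexicographically; words
#' never observed are omitted, so fewer than `k` rows may return.
#'
#' @param docs Tibble with a `tokens` list-column, or list of token
#'   vectors.
#' @param lexicon An [emotion_lexicon()].
#' @param emotion One of [emotion_categories()].
#' @param k Number of keywords (default 10).
#' @return Tibble `word`, `frequency`, `pos_class`, `intensity`.
#' @export
top_keywords <- function(docs, lexicon, emotion, k = 10L) {
  stopifnot(k >= 1)
  if (!(emotion %in% emotion_categories())) {
    stop("unknown emotion category: ", emotion, call. = FALSE)
  }
  toks <- if (is.data.frame(docs)) docs$tokens else docs
  e <- lexicon$entries
  cat_words <- e$word[e$emotion == emotion]
  if (length(cat_words) == 0) {
    return(tibble::tibble(word = character(), frequency = integer(),
                          pos_class = character(), intensity = integer()))
  }
  all_tokens <- unlist(toks, use.names = FALSE)
  freq <- table(all_tokens[all_tokens %in% cat_words])
  if (length(freq) == 0) {
    return(tibble::tibble(word = character(), frequency = integer(),
                          pos_class = character(), intensity = integer()))
  }
  df <- tibble::tibble(word = names(freq), frequency = as.integer(freq))
  ord <- order(-df$frequency, df$word, method = "radix")
  df <- df[ord, ][seq_len(min(k, nrow(df))), ]
  i <- match(df$word, e$word)
  df$pos_class <- e$pos_class[i]
  df$intensity <- e$intensity[i]
  df
}
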