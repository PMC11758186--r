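# URL characters: the ASCII set usual in links; deliberately excludes CJK
# so that text glued directly onto a URL survives cleaning.
url_pattern <- function() {
  "(?i)\\b(?:https?|ftp)://[-A-Za-z0-9._~:/?#@!$&'()*+,;=%\\[\\]]*"
}
www_pattern <- function() {
  "(?i)\\bwww\\.[-A-Za-z0-9._~:/?#@!$&'()*+,;=%\\[\\]]*"
}

#' Clean raw microblog text
#'
#' Removes, in order: URLs (scheme- or `www.`-prefixed), HTML tags
#' (non-greedy angle-bracket spans), and every character that is not a
#' Unicode letter, digit or CJK ideograph. Letters, digits and ideographs
#' are preserved in their original order; whitespace, punctuation, emoji
#' and other symbols are dropped. The operation is idempotent.
#'
#' @param text Character vector (NA treated as empty).
#' @return Character vector of the same length.
#' @export
#' @examples
#' clean_text("<b>专家</b>说: http://t.cn/Rx1 好!!")
clean_text <- function(text) {
  x <- as.character(text)
  x[is.na(x)] <- ""
  x <- gsub(url_pattern(), "", x, perl = TRUE)
  x <- gsub(www_pattern(), "", x, perl = TRUE)
  x <- gsub("<[^>]*>", "", x, perl = TRUE)
  # keep Unicode letters (includes CJK ideographs, category Lo) and digits
  x <- gsub("[^\\p{L}\\p{N}]+", "", x, perl = TRUE)
  x
}

#' Apply the minimum-length validity filter
#'
#' Posts whose cleaned text is shorter than `min_chars` characters
#' (Unicode code points) are considered invalid and dropped; the boundary
#' is inclusive (exactly `min_chars` characters is retained). By default
#' the filter counts characters of the *cleaned* text, so that posts made
#' of little besides a long URL are dropped; set `on_cleaned = FALSE` to
#' count raw characters instead.
#'
#' @param posts Data frame with columns `post_id`, `timestamp`, `text`.
#' @param min_chars Minimum number of characters (default 10).
#' @param on_cleaned Count characters after [clean_text()] (default TRUE).
#' @return List with `retained` (tibble) and `dropped_count` (integer).
#' @export
filter_valid <- function(posts, min_chars = 10L, on_cleaned = TRUE) {
  stopifnot(min_chars >= 0)
  posts <- tibble::as_tibble(posts)
  if (nrow(posts) == 0) {
    return(list(retained = posts, dropped_count = 0L))
  }
  n <- if (on_cleaned) nchar(clean_text(posts$text)) else nchar(posts$text)
  keep <- n >= min_chars
  list(retained = posts[keep, , drop = FALSE],
       dropped_count = sum(!keep))
}

#' Segment text by forward maximum matching
#'
#' Deterministic dictionary-driven segmentation: scanning left to right,
#' at each position the longest word from the combined dictionary
#' (lexicon vocabulary plus `user_dict`) starting there is emitted; if no
#' dictionary word starts there, the single character is emitted and the
#' scan advances one position. Tokenization is lossless: the
#' concatenation of the returned tokens reproduces the input exactly.
#'
#' This is the package's reference tokenizer; an external segmenter can be
#' substituted anywhere a token list is consumed.
#'
#' @param text Single (already cleaned) character string.
#' @param lexicon Optional [emotion_lexicon()] supplying dictionary words.
#' @param user_dict Optional character vector of extra dictionary words.
#' @return Character vector of tokens (`character(0)` for empty input).
#' @export
#' @examples
#' lex <- emotion_lexicon(data.frame(
#'   word = "专家", pos_class = "noun", emotion = "Good",
#'   intensity = 5L, polarity = 1L
#' ))
#' tokenize("专家说", lex)
tokenize <- function(text, lexicon = NULL, user_dict = NULL) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  vocab <- c(if (!is.null(lexicon)) lexicon$vocabulary, user_dict)
  tokenize_fmm(text, vocab)
}

tokenize_fmm <- function(text, vocab) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0) return(character(0))
  if (length(vocab) == 0) return(chars)
  maxlen <- max(nchar(vocab))
  dict <- new.env(hash = TRUE, parent = emptyenv(), size = length(vocab) * 2L)
  for (w in vocab) assign(w, TRUE, envir = dict)
  out <- character(n)
  n_out <- 0L
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (len in seq.int(min(maxlen, n - i + 1L), 1L)) {
      if (len == 1L) break
      cand <- paste(chars[i:(i + len - 1L)], collapse = "")
      if (exists(cand, envir = dict, inherits = FALSE)) {
        hit <- cand
        break
      }
    }
    if (is.null(hit)) hit <- chars[i]
    n_out <- n_out + 1L
    out[n_out] <- hit
    i <- i + nchar(hit)
  }
  out[seq_len(n_out)]
}

#' Remove stop words from a token list
#'
#' @param tokens Character vector of tokens.
#' @param stopwords A [stopword_list()] (or plain character vector).
#' @return Tokens with all stop words deleted, order preserved.
#' @export
remove_stopwords <- function(tokens, stopwords) {
  sw <- if (inherits(stopwords, "stopword_list")) stopwords$tokens else stopwords
  tokens[!(tokens %in% sw)]
}

#' Run the full preprocessing stage over a corpus
#'
#' clean -> length filter -> forward-maximum-matching segmentation ->
#' stop-word removal. Deterministic: identical inputs and options yield
#' identical output.
#'
#' @param posts Data frame with `post_id`, `timestamp`, `text`.
#' @param lexicon [emotion_lexicon()] used as segmentation dictionary.
#' @param stopwords Optional [stopword_list()].
#' @param user_dict Optional extra dictionary words for the tokenizer.
#' @param min_chars Validity threshold passed to [filter_valid()].
#' @param on_cleaned Whether the length filter counts cleaned characters.
#' @return List with `docs` (tibble: `post_id`, `timestamp`, `tokens`
#'   list-column, `cleaned_length`) and `dropped_count`.
#' @export
preprocess_corpus <- function(posts, lexicon, stopwords = NULL,
                              user_dict = NULL, min_chars = 10L,
                              on_cleaned = TRUE) {
  flt <- filter_valid(posts, min_chars = min_chars, on_cleaned = on_cleaned)
  kept <- flt$retained
  cleaned <- clean_text(kept$text)
  toks <- lapply(cleaned, tokenize, lexicon = lexicon, user_dict = user_dict)
  if (!is.null(stopwords)) {
    toks <- lapply(toks, remove_stopwords, stopwords = stopwords)
  }
  docs <- tibble::tibble(
    post_id = as.character(kept$post_id),
    timestamp = as.character(kept$timestamp),
    tokens = toks,
    cleaned_length = nchar(cleaned)
  )
  list(docs = docs, dropped_count = flt$dropped_count)
}
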