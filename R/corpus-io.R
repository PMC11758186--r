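#' Read a post corpus
#'
#' Reads one record per post with fields `post_id`, `timestamp` (ISO-8601
#' string) and `text`, either from JSON Lines (one object per line) or
#' CSV. Format is inferred from the extension unless given.
#'
#' @param path File to read.
#' @param format `"auto"`, `"jsonl"` or `"csv"`.
#' @return Tibble with character columns `post_id`, `timestamp`, `text`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          fileEncoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    df <- data.frame(
      post_id = vapply(recs, function(r) as.character(r$post_id), ""),
      timestamp = vapply(recs, function(r) as.character(r$timestamp), ""),
      text = vapply(recs, function(r) as.character(r$text), ""),
      stringsAsFactors = FALSE
    )
  }
  need <- c("post_id", "timestamp", "text")
  if (!all(need %in% names(df))) {
    stop("corpus format error: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$post_id)) {
    stop("corpus validation error: duplicate post_id", call. = FALSE)
  }
  tibble::as_tibble(df[, need])
}

#' Write a post corpus
#'
#' @param posts Data frame with `post_id`, `timestamp`, `text`.
#' @param path Destination file.
#' @param format `"auto"`, `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(posts, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  posts <- as.data.frame(posts)[, c("post_id", "timestamp", "text")]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "csv") {
    utils::write.csv(posts, con, row.names = FALSE)
  } else {
    for (i in seq_len(nrow(posts))) {
      writeLines(jsonlite::toJSON(
        list(post_id = posts$post_id[i], timestamp = posts$timestamp[i],
             text = posts$text[i]),
        auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

# Tokenized-document JSONL: post_id, timestamp, cleaned_length, tokens[].
write_tokenized <- function(docs, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(docs))) {
    writeLines(jsonlite::toJSON(
      list(post_id = docs$post_id[i], timestamp = docs$timestamp[i],
           cleaned_length = docs$cleaned_length[i],
           tokens = docs$tokens[[i]]),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

read_tokenized <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    post_id = vapply(recs, function(r) as.character(r$post_id), ""),
    timestamp = vapply(recs, function(r) as.character(r$timestamp), ""),
    tokens = lapply(recs, function(r) as.character(r$tokens)),
    cleaned_length = vapply(recs, function(r) as.integer(r$cleaned_length), 0L)
  )
}
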