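lexicon_columns <- function() {
  c("word", "pos_class", "emotion", "subcategory", "intensity", "polarity",
    "aux_emotion", "aux_intensity", "aux_polarity")
}

#' Construct a validated affect lexicon
#'
#' An `emotion_lexicon` is the in-memory form of a DUTIR-style affect
#' dictionary: one primary record per word carrying a part-of-speech
#' class, an emotion category (one of the seven in
#' [emotion_categories()]), an optional subcategory label, an intensity
#' level in \{1, 3, 5, 7, 9\} (9 strongest) and a polarity code in
#' \{0, 1, 2, 3\} (neutral / positive / negative / both). A word may
#' additionally carry one auxiliary emotion with its own intensity and
#' polarity. Polarity and subcategory are stored and reported but play no
#' role in emotion scoring, which operates purely on the seven-category
#' level.
#'
#' @param entries Data frame with columns `word`, `pos_class`, `emotion`,
#'   `intensity`, `polarity`, and optionally `subcategory`, `aux_emotion`,
#'   `aux_intensity`, `aux_polarity` (missing optional columns are filled
#'   with `NA`).
#' @return An object of class `emotion_lexicon` with fields `entries`
#'   (tibble), `vocabulary` (character) and `max_word_length` (integer,
#'   characters).
#' @export
#' @examples
#' lex <- emotion_lexicon(data.frame(
#'   word = c("希望", "恐慌"),
#'   pos_class = c("verb", "noun"),
#'   emotion = c("Good", "Fear"),
#'   intensity = c(5L, 7L),
#'   polarity = c(1L, 2L)
#' ))
#' lex$max_word_length
emotion_lexicon <- function(entries = NULL) {
  if (is.null(entries)) {
    entries <- data.frame(
      word = character(), pos_class = character(), emotion = character(),
      intensity = integer(), polarity = integer(),
      stringsAsFactors = FALSE
    )
  }
  entries <- tibble::as_tibble(entries)
  required <- c("word", "pos_class", "emotion", "intensity", "polarity")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    stop("lexicon format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("subcategory", "aux_emotion")) {
    if (is.null(entries[[col]])) entries[[col]] <- rep(NA_character_, nrow(entries))
  }
  for (col in c("aux_intensity", "aux_polarity")) {
    if (is.null(entries[[col]])) entries[[col]] <- rep(NA_integer_, nrow(entries))
  }
  entries$word <- as.character(entries$word)
  entries$pos_class <- as.character(entries$pos_class)
  entries$emotion <- as.character(entries$emotion)
  entries$subcategory <- as.character(entries$subcategory)
  entries$aux_emotion <- as.character(entries$aux_emotion)
  entries$intensity <- coerce_int(entries$intensity, "intensity")
  entries$polarity <- coerce_int(entries$polarity, "polarity")
  entries$aux_intensity <- coerce_int(entries$aux_intensity, "aux_intensity")
  entries$aux_polarity <- coerce_int(entries$aux_polarity, "aux_polarity")
  entries <- entries[, lexicon_columns()]
  validate_lexicon_entries(entries)
  structure(
    list(
      entries = entries,
      vocabulary = entries$word,
      max_word_length = if (nrow(entries)) max(nchar(entries$word)) else 0L
    ),
    class = "emotion_lexicon"
  )
}

coerce_int <- function(x, what) {
  if (is.integer(x)) return(x)
  xn <- suppressWarnings(as.numeric(as.character(x)))
  bad <- which(!is.na(x) & nzchar(trimws(as.character(x))) & is.na(xn))
  if (length(bad) > 0) {
    stop(sprintf("lexicon validation error: non-numeric %s at row %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  as.integer(round(xn))
}

validate_lexicon_entries <- function(entries) {
  fail <- function(rows, msg) {
    stop(sprintf("lexicon validation error: %s at row %s", msg,
                 paste(rows, collapse = ", ")), call. = FALSE)
  }
  if (nrow(entries) == 0) return(invisible(TRUE))
  bad <- which(is.na(entries$word) | !nzchar(entries$word) |
                 grepl("\\s", entries$word))
  if (length(bad)) fail(bad, "empty or whitespace-containing word")
  dup <- which(duplicated(entries$word))
  if (length(dup)) {
    fail(dup, sprintf("duplicate word(s) %s",
                      paste(unique(entries$word[dup]), collapse = ", ")))
  }
  bad <- which(!(entries$pos_class %in% pos_classes()))
  if (length(bad)) fail(bad, "unknown pos_class")
  bad <- which(!(entries$emotion %in% emotion_categories()))
  if (length(bad)) fail(bad, "unknown emotion category")
  bad <- which(is.na(entries$intensity) |
                 !(entries$intensity %in% intensity_levels()))
  if (length(bad)) fail(bad, "intensity not in {1,3,5,7,9}")
  bad <- which(is.na(entries$polarity) |
                 !(entries$polarity %in% polarity_codes()))
  if (length(bad)) fail(bad, "polarity not in {0,1,2,3}")
  has_aux <- !is.na(entries$aux_emotion)
  # auxiliary triple must be complete and satisfy the same constraints
  bad <- which(has_aux & (is.na(entries$aux_intensity) |
                            is.na(entries$aux_polarity)))
  bad <- union(bad, which(!has_aux & (!is.na(entries$aux_intensity) |
                                        !is.na(entries$aux_polarity))))
  if (length(bad)) fail(sort(bad), "incomplete aux_emotion triple")
  bad <- which(has_aux & !(entries$aux_emotion %in% emotion_categories()))
  if (length(bad)) fail(bad, "unknown aux_emotion category")
  bad <- which(has_aux & !(entries$aux_intensity %in% intensity_levels()))
  if (length(bad)) fail(bad, "aux_intensity not in {1,3,5,7,9}")
  bad <- which(has_aux & !(entries$aux_polarity %in% polarity_codes()))
  if (length(bad)) fail(bad, "aux_polarity not in {0,1,2,3}")
  invisible(TRUE)
}

#' @export
print.emotion_lexicon <- function(x, ...) {
  cat(sprintf("<emotion_lexicon> %d words, max word length %d\n",
              nrow(x$entries), x$max_word_length))
  tab <- table(factor(x$entries$emotion, levels = emotion_categories()))
  cat(paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Load an affect lexicon from a delimited file
#'
#' Reads a UTF-8 tab- or comma-separated file with one header row and the
#' columns `word`, `pos_class`, `emotion`, `intensity`, `polarity` plus
#' optional `subcategory`, `aux_emotion`, `aux_intensity`, `aux_polarity`
#' (blank cells mean absent). Emotion labels are mapped through `aliases`
#' so a DUTIR-style dictionary exported with its native category codes can
#' be loaded after a one-time column mapping. All domain constraints are
#' validated exhaustively; malformed rows are reported with their row
#' number (header excluded).
#'
#' @param path File to read.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param aliases Named character vector mapping source emotion labels to
#'   canonical categories; see [default_emotion_aliases()].
#' @return An [emotion_lexicon()] object.
#' @export
load_lexicon <- function(path, dialect = c("tsv", "csv"),
                         aliases = default_emotion_aliases()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(
    path, sep = sep, header = TRUE, quote = "", comment.char = "",
    colClasses = "character", stringsAsFactors = FALSE,
    fileEncoding = "UTF-8", na.strings = NULL, check.names = TRUE
  )
  required <- c("word", "pos_class", "emotion", "intensity", "polarity")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("lexicon format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  blank_to_na <- function(x) {
    x <- trimws(x)
    x[!nzchar(x)] <- NA_character_
    x
  }
  for (col in intersect(lexicon_columns(), names(raw))) {
    raw[[col]] <- blank_to_na(raw[[col]])
  }
  mapped <- canonical_emotion(raw$emotion, aliases)
  bad <- which(is.na(mapped) & !is.na(raw$emotion))
  if (length(bad)) {
    stop(sprintf("lexicon validation error: unknown emotion label at row %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  raw$emotion <- mapped
  if (!is.null(raw$aux_emotion)) {
    has_aux <- !is.na(raw$aux_emotion)
    mapped_aux <- canonical_emotion(raw$aux_emotion, aliases)
    bad <- which(is.na(mapped_aux) & has_aux)
    if (length(bad)) {
      stop(sprintf(
        "lexicon validation error: unknown aux_emotion label at row %s",
        paste(bad, collapse = ", ")), call. = FALSE)
    }
    raw$aux_emotion <- mapped_aux
  }
  emotion_lexicon(raw)
}

#' Write an affect lexicon to a delimited file
#'
#' Emits the fixed tabular dialect read by [load_lexicon()]: UTF-8, one
#' header row, blank cells for absent optional fields. The written file
#' round-trips (`load_lexicon(write_lexicon(x)) == x`).
#'
#' @param lexicon An [emotion_lexicon()] object.
#' @param path Destination file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(lexicon, "emotion_lexicon"))
  sep <- if (dialect == "tsv") "\t" else ","
  df <- as.data.frame(lexicon$entries)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "")
  invisible(path)
}

#' Look up the emotion attributions of a token
#'
#' Returns zero, one or two `(emotion, intensity, polarity)` attributions
#' for a token: the primary record first, then the auxiliary one if the
#' word carries it. Unknown tokens yield an empty result. The lookup is a
#' pure function of `(lexicon, token)`.
#'
#' @param lexicon An [emotion_lexicon()].
#' @param token Single character string.
#' @return Tibble with columns `emotion`, `intensity`, `polarity`,
#'   `source` (`"primary"` or `"aux"`), 0-2 rows.
#' @export
lookup <- function(lexicon, token) {
  stopifnot(inherits(lexicon, "emotion_lexicon"),
            is.character(token), length(token) == 1L)
  empty <- tibble::tibble(
    emotion = character(), intensity = integer(), polarity = integer(),
    source = character()
  )
  i <- match(token, lexicon$entries$word)
  if (is.na(i)) return(empty)
  e <- lexicon$entries[i, ]
  out <- tibble::tibble(
    emotion = e$emotion, intensity = e$intensity, polarity = e$polarity,
    source = "primary"
  )
  if (!is.na(e$aux_emotion)) {
    out <- rbind(out, tibble::tibble(
      emotion = e$aux_emotion, intensity = e$aux_intensity,
      polarity = e$aux_polarity, source = "aux"
    ))
  }
  out
}

#' Construct a stop-word list
#'
#' @param tokens Character vector; empty strings are rejected.
#' @return Object of class `stopword_list`.
#' @export
stopword_list <- function(tokens = character()) {
  tokens <- as.character(tokens)
  if (any(is.na(tokens) | !nzchar(tokens))) {
    stop("stopword_list: empty strings are not allowed", call. = FALSE)
  }
  structure(list(tokens = unique(tokens)), class = "stopword_list")
}

#' Load a stop-word list from plain text
#'
#' One token per line, UTF-8; `#` starts a comment; blank lines ignored.
#'
#' @param path File to read.
#' @return A [stopword_list()].
#' @export
load_stopwords <- function(path) {
  if (!file.exists(path)) stop("stop-word file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  stopword_list(lines[nzchar(lines)])
}
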