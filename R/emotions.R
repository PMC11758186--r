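#' Canonical emotion categories
#'
#' The seven affect categories used throughout the package, in a fixed
#' canonical order (Good, Happy, Anger, Disgust, Sadness, Surprise, Fear).
#' The order doubles as the deterministic tie-break rule: when two
#' categories reach exactly the same score for a document, the one listed
#' first wins.
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' emotion_categories()
emotion_categories <- function() {
  c("Good", "Happy", "Anger", "Disgust", "Sadness", "Surprise", "Fear")
}

#' Part-of-speech classes recognised in the affect lexicon
#'
#' Seven classes mirroring the structure of DUTIR-style affect
#' dictionaries: noun, verb, adjective, adverb, network word, idiom and
#' prepositional phrase.
#'
#' @return Character vector of length 7.
#' @export
pos_classes <- function() {
  c("noun", "verb", "adj", "adv", "network_word", "idiom", "prep_phrase")
}

# Valid emotional-intensity levels (9 strongest, 1 weakest).
intensity_levels <- function() c(1L, 3L, 5L, 7L, 9L)

# Polarity codes: 0 neutral, 1 positive, 2 negative, 3 both.
polarity_codes <- function() 0:3

#' Default emotion-label alias table
#'
#' Maps native category labels of a DUTIR-style dictionary (including the
#' Chinese single-character majors) and common lower-case spellings onto
#' the canonical English tokens used by this package. Users can extend or
#' replace the table via the `aliases` argument of [load_lexicon()].
#'
#' @return Named character vector: names are accepted source labels,
#'   values are canonical categories.
#' @export
default_emotion_aliases <- function() {
  canon <- emotion_categories()
  c(
    setNames(canon, canon),
    setNames(canon, tolower(canon)),
    setNames(
      c("Happy", "Good", "Anger", "Sadness", "Fear", "Disgust", "Surprise"),
      c("\u4e50", "\u597d", "\u6012", "\u54c0", "\u60e7", "\u6076", "\u60ca")
    )
  )
}

# Map raw emotion labels to canonical ones; returns NA where unknown.
canonical_emotion <- function(x, aliases = default_emotion_aliases()) {
  out <- unname(aliases[as.character(x)])
  out
}
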