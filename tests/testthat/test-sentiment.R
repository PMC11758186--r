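test_that("match_emotions sums intensities per category and picks the dominant", {
  lex <- emotion_lexicon(data.frame(
    word = c("希望", "恐慌"),
    pos_class = c("verb", "noun"),
    emotion = c("Good", "Fear"),
    intensity = c(5L, 7L),
    polarity = c(1L, 2L)
  ))
  p <- match_emotions(c("希望", "希望", "恐慌"), lex)
  expect_equal(p$scores[["Good"]], 10)
  expect_equal(p$scores[["Fear"]], 7)
  expect_equal(p$counts[["Good"]], 2L)
  expect_equal(p$dominant, "Good")
  # repeated tokens count each occurrence; non-lexicon tokens are ignored
  expect_equal(sum(p$counts), 3L)

  none <- match_emotions(c("无", "关"), lex)
  expect_true(all(none$counts == 0))
  expect_equal(none$dominant, "none")

  # exact tie resolves by canonical category order (Good before Fear)
  tie <- emotion_lexicon(data.frame(
    word = c("甲甲", "乙乙"), pos_class = "noun",
    emotion = c("Good", "Fear"), intensity = c(5L, 5L), polarity = c(1L, 2L)
  ))
  expect_equal(match_emotions(c("甲甲", "乙乙"), tie)$dominant, "Good")
  # and Anger before Sadness, per the full order
  tie2 <- emotion_lexicon(data.frame(
    word = c("丙丙", "丁丁"), pos_class = "noun",
    emotion = c("Sadness", "Anger"), intensity = c(3L, 3L), polarity = 2L
  ))
  expect_equal(match_emotions(c("丙丙", "丁丁"), tie2)$dominant, "Anger")
})

test_that("auxiliary attributions are counted when enabled and skipped when not", {
  lex <- toy_lexicon()
  w <- toy_word("Good", 2) # carries aux (Happy, 3)
  with_aux <- match_emotions(c(w), lex, use_aux = TRUE)
  expect_equal(with_aux$counts[["Happy"]], 1L)
  expect_equal(with_aux$scores[["Happy"]], 3)
  without <- match_emotions(c(w), lex, use_aux = FALSE)
  expect_equal(without$counts[["Happy"]], 0L)
  # each token contributes at most primary + auxiliary
  expect_lte(sum(with_aux$counts), 2L)
})

test_that("count and intensity weighting agree when all intensities are equal", {
  lex <- emotion_lexicon(data.frame(
    word = c("aa", "bb", "cc"), pos_class = "noun",
    emotion = c("Good", "Anger", "Fear"), intensity = 5L,
    polarity = c(1L, 2L, 2L)
  ))
  set.seed(9)
  for (i in 1:20) {
    toks <- sample(c("aa", "bb", "cc", "xx"), sample(3:12, 1), replace = TRUE)
    d1 <- match_emotions(toks, lex, weighting = "intensity")$dominant
    d2 <- match_emotions(toks, lex, weighting = "count")$dominant
    expect_identical(d1, d2)
  }
})

test_that("classify_corpus preserves order and recovers pure planted labels", {
  lex <- toy_lexicon()
  docs <- tibble::tibble(
    post_id = c("p1", "p2", "p3"),
    tokens = list(
      c(toy_word("Anger", 1), toy_word("Anger", 1)),
      c(toy_word("Surprise", 1)),
      c("无", "关")
    )
  )
  prof <- classify_corpus(docs, lex)
  expect_equal(prof$post_id, c("p1", "p2", "p3"))
  expect_equal(prof$dominant, c("Anger", "Surprise", "none"))
  expect_equal(nrow(classify_corpus(docs[0, ], lex)), 0)
})

test_that("corpus proportions follow the reporting convention for neutral posts", {
  s <- corpus_proportions(c("Good", "Good", "Fear"))
  expect_equal(s$proportions[["Good"]], 2 / 3)
  expect_equal(s$proportions[["Fear"]], 1 / 3)
  expect_equal(sum(s$proportions), 1, tolerance = 1e-9)
  expect_equal(s$n_classified, 3L)

  with_none <- corpus_proportions(c("Good", "none", "none", "Fear"),
                                  include_neutral = TRUE)
  expect_equal(with_none$proportions[["none"]], 0.5)
  expect_equal(sum(with_none$proportions), 1, tolerance = 1e-9)

  expect_warning(deg <- corpus_proportions(c("none", "none")), "no classified")
  expect_true(deg$degenerate)
  expect_true(all(deg$proportions == 0))
  expect_equal(deg$n_neutral, 2L)
})

test_that("top_keywords equals a brute-force count-and-sort", {
  cfg <- generator_config(seed = 13, n_docs = 120)
  lex <- generate_lexicon(cfg)
  corp <- generate_corpus(cfg, lex)
  toks <- corp$tokens
  for (emo in c("Good", "Fear", "Surprise")) {
    got <- top_keywords(toks, lex, emo, k = 10)
    # brute force: count every occurrence of each category word
    words <- lex$entries$word[lex$entries$emotion == emo]
    all_t <- unlist(toks)
    freq <- vapply(words, function(w) sum(all_t == w), 0L)
    freq <- freq[freq > 0]
    ord <- order(-freq, names(freq), method = "radix")
    expected <- names(freq)[ord][seq_len(min(10, length(freq)))]
    expect_equal(got$word, expected)
    expect_equal(got$frequency,
                 unname(freq[ord])[seq_len(min(10, length(freq)))])
    expect_true(all(got$intensity %in% c(1, 3, 5, 7, 9)))
    expect_true(all(got$frequency >= 1))
  }
  # k larger than observed vocabulary: shorter list, no padding
  few <- top_keywords(list(c(toy_word("Good", 1))), toy_lexicon(),
                      "Good", k = 10)
  expect_equal(nrow(few), 1)
  # category with zero matches
  expect_equal(nrow(top_keywords(list("xx"), toy_lexicon(), "Fear")), 0)
  expect_error(top_keywords(toks, lex, "Joy"), "unknown emotion")
})
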