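test_that("generator_config validates its stated world", {
  cfg <- generator_config(seed = 1)
  expect_equal(sum(cfg$emotion_mix), 1, tolerance = 1e-9)
  expect_named(cfg$emotion_mix, emotion_categories())
  expect_equal(length(cfg$daily_profile), length(cfg$days))
  expect_error(generator_config(emotion_mix = c(Good = 1)), "emotion_mix")
  expect_error(generator_config(contamination = 1.5), "rates")
  expect_error(generator_config(doc_length = c(10, 5)), "doc_length")
  expect_error(generator_config(date_range = c("2023-01-01", "2022-01-01")),
               "date_range")
})

test_that("generated lexicons satisfy every domain invariant and round-trip", {
  cfg <- generator_config(seed = 6)
  lex <- generate_lexicon(cfg)
  e <- lex$entries
  expect_equal(nrow(e), 7 * cfg$words_per_category)
  expect_setequal(unique(e$emotion), emotion_categories())
  expect_setequal(unique(e$pos_class), pos_classes())
  expect_true(all(e$intensity %in% c(1, 3, 5, 7, 9)))
  # polarity follows category valence
  expect_true(all(e$polarity[e$emotion %in% c("Good", "Happy")] == 1))
  expect_true(all(e$polarity[e$emotion %in%
                               c("Anger", "Sadness", "Fear", "Disgust")] == 2))
  expect_true(all(e$polarity[e$emotion == "Surprise"] == 3))
  # determinism
  expect_identical(generate_lexicon(cfg), generate_lexicon(cfg))
  # different seed, different words
  lex2 <- generate_lexicon(generator_config(seed = 7))
  expect_false(identical(lex$vocabulary, lex2$vocabulary))
  # write/load round trip, including aux columns
  expect_true(any(!is.na(e$aux_emotion)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  expect_equal(load_lexicon(path)$entries, e)
})

test_that("generated corpora are pure functions of the config", {
  cfg <- generator_config(seed = 12, n_docs = 80)
  lex <- generate_lexicon(cfg)
  c1 <- generate_corpus(cfg, lex)
  c2 <- generate_corpus(cfg, lex)
  expect_identical(c1$posts, c2$posts)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$phi_true, c2$phi_true)
  expect_equal(nrow(c1$posts), 80)
  # empty corpus edge
  c0 <- generate_corpus(generator_config(seed = 1, n_docs = 0), lex)
  expect_equal(nrow(c0$posts), 0)
})

test_that("planted topic rows are distributions with controlled overlap", {
  cfg <- generator_config(seed = 3, n_docs = 10, vocab_overlap = 0)
  corp <- generate_corpus(cfg, generate_lexicon(cfg))
  expect_true(all(abs(rowSums(corp$phi_true) - 1) < 1e-9))
  supports <- lapply(1:3, function(k) which(corp$phi_true[k, ] > 0))
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_length(intersect(supports[[i]], supports[[j]]), 0)
    }
  }
  cfg2 <- generator_config(seed = 3, n_docs = 10, vocab_overlap = 0.5)
  corp2 <- generate_corpus(cfg2, generate_lexicon(cfg2))
  sup2 <- lapply(1:3, function(k) which(corp2$phi_true[k, ] > 0))
  shared <- Reduce(intersect, sup2)
  expect_gte(length(shared), round(0.5 * cfg2$V) - 1)
})

test_that("planted dominant labels are strict winners and follow the emotion mix", {
  cfg <- generator_config(seed = 19, n_docs = 5000, contamination = 0.1,
                          neutral_rate = 0.05)
  lex <- generate_lexicon(cfg)
  corp <- generate_corpus(cfg, lex)
  # classifier recovers every planted label under both scoring modes
  docs <- tibble::tibble(post_id = corp$truth$post_id, tokens = corp$tokens)
  for (w in c("intensity", "count")) {
    prof <- classify_corpus(docs, lex, weighting = w)
    expect_equal(mean(prof$dominant == corp$truth$emotion), 1)
  }
  # empirical dominant shares converge to the configured mix
  lab <- corp$truth$emotion[corp$truth$emotion != "none"]
  shares <- table(factor(lab, levels = emotion_categories())) / length(lab)
  expect_lt(max(abs(as.numeric(shares) - cfg$emotion_mix)), 0.02)
  # neutral rate respected in expectation
  expect_equal(mean(corp$truth$emotion == "none"), 0.05, tolerance = 0.02)
})

test_that("timestamps follow the configured daily profile", {
  profile <- c(1, 1, 8, 1, 1)
  cfg <- generator_config(
    seed = 9, n_docs = 2000,
    date_range = c("2022-12-01", "2022-12-05"),
    daily_profile = profile
  )
  corp <- generate_corpus(cfg, generate_lexicon(cfg))
  ds <- daily_counts(corp$posts)
  expect_equal(sum(ds$series$n), 2000)
  # chi-square goodness of fit against the configured profile
  expected <- profile / sum(profile) * 2000
  chi2 <- sum((ds$series$n - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 4))
  # the spike day is the unique detected peak
  expect_equal(ds$peaks, as.Date("2022-12-03"))
})

test_that("simulated annotators degrade from perfect to near-chance agreement", {
  truth <- sample(emotion_categories(), 400, replace = TRUE)
  perfect <- generate_annotations(truth, 0, seed = 5)
  expect_identical(perfect$a, truth)
  expect_identical(perfect$b, truth)
  expect_equal(cohen_kappa(perfect$a, perfect$b)$kappa, 1)
  # determinism
  again <- generate_annotations(truth, 0.3, seed = 8)
  expect_identical(again, generate_annotations(truth, 0.3, seed = 8))
  # full corruption over 7 categories: analytic kappa is
  # (1/6 - 1/7) / (1 - 1/7) ~= 0.028; check within Monte-Carlo tolerance
  set.seed(2)
  truth_big <- sample(emotion_categories(), 10000, replace = TRUE)
  noisy <- generate_annotations(truth_big, 1, seed = 3)
  expect_false(any(noisy$a == truth_big))
  k <- cohen_kappa(noisy$a, noisy$b)$kappa
  expect_lt(abs(k - (1 / 6 - 1 / 7) / (1 - 1 / 7)), 0.03)
  # moderate error keeps agreement well above chance
  mid <- generate_annotations(truth_big, 0.1, seed = 4)
  expect_gt(cohen_kappa(mid$a, mid$b)$kappa, 0.7)
})
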