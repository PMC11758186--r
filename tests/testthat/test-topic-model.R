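# small deterministic bag-of-words fixture over V = 4
tiny_bow <- function() {
  vocab <- c("w1", "w2", "w3", "w4")
  make_bow(list(c("w1", "w2", "w1"), c("w3", "w4", "w4", "w2")),
           vocabulary = vocab)
}

test_that("make_bow indexes tokens against a deterministic vocabulary", {
  bow <- tiny_bow()
  expect_equal(bow$M, 2)
  expect_equal(bow$V, 4)
  expect_equal(bow$N_d, c(3L, 4L))
  expect_equal(bow$docs[[1]], c(1L, 2L, 1L))
  # auto-vocabulary is byte-sorted and stable
  auto <- make_bow(list(c("b", "a"), c("c", "a")))
  expect_equal(auto$vocabulary, c("a", "b", "c"))
})

test_that("perplexity matches the brute-force oracle on hand-fixed models", {
  bow <- tiny_bow()
  set.seed(42)
  for (i in 1:10) {
    K <- sample(2:4, 1)
    phi <- matrix(rgamma(K * 4, 1), K, 4)
    phi <- phi / rowSums(phi)
    theta <- matrix(rgamma(2 * K, 1), 2, K)
    theta <- theta / rowSums(theta)
    model <- lda_model(phi, theta)
    got <- perplexity(model, bow)
    expect_equal(got$perplexity, perplexity_oracle(phi, theta, bow$docs),
                 tolerance = 1e-12)
    expect_equal(got$log_perplexity, log(got$perplexity), tolerance = 1e-12)
    expect_gte(got$perplexity, 1)
  }
})

test_that("perplexity closed forms: uniform model gives V, degenerate model gives 1", {
  for (V in c(2, 10, 100)) {
    vocab <- paste0("w", seq_len(V))
    docs <- list(vocab[c(1, min(2, V))], vocab[1])
    bow <- make_bow(docs, vocabulary = vocab)
    uniform <- lda_model(matrix(1 / V, 1, V), matrix(1, bow$M, 1))
    expect_equal(perplexity(uniform, bow)$perplexity, V, tolerance = 1e-12)
  }
  # model assigning probability 1 to the only observed token
  bow1 <- make_bow(list(c("a", "a"), "a"), vocabulary = c("a", "b"))
  degen <- lda_model(matrix(c(1, 0), 1, 2), matrix(1, 2, 1))
  expect_equal(perplexity(degen, bow1)$perplexity, 1, tolerance = 1e-12)
})

test_that("fit_lda is deterministic under a fixed seed and conserves counts", {
  cfg <- generator_config(seed = 2, n_docs = 60, neutral_rate = 1)
  corp <- generate_corpus(cfg, generate_lexicon(cfg))
  bow <- make_bow(corp$tokens)
  f1 <- fit_lda(bow, 3, iterations = 60, burn_in = 20, seed = 99)
  f2 <- fit_lda(bow, 3, iterations = 60, burn_in = 20, seed = 99)
  expect_identical(f1$z, f2$z)
  expect_identical(f1$phi, f2$phi)
  expect_identical(f1$theta, f2$theta)
  expect_true(all(f1$counts_conserved))
  # row stochasticity
  expect_true(all(abs(rowSums(f1$phi) - 1) < 1e-9))
  expect_true(all(abs(rowSums(f1$theta) - 1) < 1e-9))
  expect_true(all(unlist(f1$z) >= 1 & unlist(f1$z) <= 3))
  # final count matrices agree with z
  expect_equal(as.integer(table(factor(unlist(f1$z), levels = 1:3))),
               f1$n_k)
  expect_error(fit_lda(bow, 0), "K must be")
  expect_error(fit_lda(make_bow(list(character(0))), 2), "empty")
})

test_that("K = 1 degenerates to the smoothed corpus unigram distribution", {
  bow <- tiny_bow()
  beta <- 0.01
  fit <- fit_lda(bow, 1, beta = beta, iterations = 20, burn_in = 5, seed = 7)
  expect_true(all(fit$theta == 1))
  n_w <- as.integer(table(factor(unlist(bow$docs), levels = 1:4)))
  expected <- (n_w + beta) / (sum(n_w) + 4 * beta)
  expect_equal(as.numeric(fit$phi), expected, tolerance = 1e-12)
})

test_that("UMass coherence matches a hand-computed value and is permutation invariant", {
  # 4 documents, hand-countable co-occurrence
  docs <- list(c("a", "b"), c("a", "b"), c("a", "c"), c("c", "d"))
  bow <- make_bow(docs) # vocabulary a,b,c,d
  # topic 1 top-2 = (a, b): D(a)=3, D(b)=2, D(a,b)=2 -> log((2+1)/3)
  # topic 2 top-2 = (c, d): D(c)=2, D(d)=1, D(c,d)=1 -> log((1+1)/2)
  phi <- rbind(c(0.6, 0.4, 0, 0), c(0, 0, 0.7, 0.3))
  theta <- matrix(0.5, 4, 2)
  model <- lda_model(phi, theta)
  expected <- mean(c(log(3 / 3), log(2 / 2)))
  expect_equal(coherence_umass(model, bow, topN = 2), expected,
               tolerance = 1e-12)
  # permuting topics leaves coherence unchanged
  model_perm <- lda_model(phi[2:1, ], theta)
  expect_equal(coherence_umass(model_perm, bow, topN = 2),
               coherence_umass(model, bow, topN = 2))
  # co-occurring pair scores positively before the +1 smoothing penalty:
  # top-2 words always co-occurring give log((D+1)/D) > 0
  both <- make_bow(list(c("x", "y"), c("x", "y", "z")))
  m2 <- lda_model(rbind(c(0.5, 0.4, 0.1)), matrix(1, 2, 1))
  expect_gt(coherence_umass(m2, both, topN = 2), 0)
})

test_that("select_k implements the peak-coherence lowest-perplexity rule", {
  rec <- function(K, coh, per) {
    data.frame(K = K, coherence = coh, perplexity = per)
  }
  # sole interior peak
  expect_equal(select_k(rec(1:3, c(0.2, 0.5, 0.3), c(9, 7, 6))), 2)
  # monotone increasing -> global maximum at the last K
  expect_equal(select_k(rec(1:4, c(0.1, 0.2, 0.3, 0.4), c(9, 8, 7, 6))), 4)
  # two equal peaks: lower perplexity wins
  expect_equal(select_k(rec(1:5, c(0.1, 0.5, 0.2, 0.5, 0.1),
                            c(10, 6, 9, 8, 7))), 2)
  expect_equal(select_k(rec(1:5, c(0.1, 0.5, 0.2, 0.5, 0.1),
                            c(10, 8, 9, 6, 7))), 4)
  # unequal peaks: the more coherent peak wins even at higher perplexity
  expect_equal(select_k(rec(1:5, c(0.1, 0.5, 0.2, 0.4, 0.1),
                            c(10, 9, 8, 1, 7))), 2)
  # equal peaks with equal perplexity: smallest K
  expect_equal(select_k(rec(1:5, c(0.1, 0.5, 0.2, 0.5, 0.1),
                            c(10, 6, 9, 6, 7))), 2)
  # single record
  expect_equal(select_k(rec(1, 0.3, 5)), 1)
  # unsorted input is sorted by K first
  expect_equal(select_k(rec(c(3, 1, 2), c(0.3, 0.2, 0.5), c(6, 9, 7))), 2)
})

test_that("sweep_k covers every K once and records both scores", {
  cfg <- generator_config(seed = 4, n_docs = 50, neutral_rate = 1,
                          doc_length = c(8L, 15L), V = 60L)
  corp <- generate_corpus(cfg, generate_lexicon(cfg))
  bow <- make_bow(corp$tokens)
  sw <- sweep_k(bow, 1:4, iterations = 40, burn_in = 10, seed = 5)
  expect_equal(sw$records$K, 1:4)
  expect_true(all(is.finite(sw$records$perplexity)))
  expect_true(all(is.finite(sw$records$coherence)))
  expect_equal(sw$records$log_perplexity, log(sw$records$perplexity))
  expect_true(sw$selected_K %in% 1:4)
  single <- sweep_k(bow, 1, iterations = 30, burn_in = 10, seed = 5)
  expect_equal(single$selected_K, 1)
  # deterministic
  sw2 <- sweep_k(bow, 1:4, iterations = 40, burn_in = 10, seed = 5)
  expect_identical(sw$records, sw2$records)
})

test_that("summarize_topics ranks keywords and computes topic intensity", {
  phi <- rbind(c(0.5, 0.3, 0.15, 0.05), c(0.05, 0.15, 0.3, 0.5))
  colnames(phi) <- c("a", "b", "c", "d")
  theta <- rbind(c(1, 0), c(0, 1))
  model <- lda_model(phi, theta)
  s <- summarize_topics(model, topN = 3)
  expect_equal(s$topics[[1]]$word, c("a", "b", "c"))
  expect_true(all(diff(s$topics[[1]]$probability) <= 0))
  expect_equal(s$intensity, c(0.5, 0.5))
  # brute-force sort agreement on a random model
  set.seed(8)
  phi2 <- matrix(rgamma(3 * 20, 1), 3, 20)
  phi2 <- phi2 / rowSums(phi2)
  colnames(phi2) <- paste0("w", 1:20)
  m2 <- lda_model(phi2, matrix(1 / 3, 5, 3))
  s2 <- summarize_topics(m2, topN = 10)
  for (k in 1:3) {
    expect_equal(s2$topics[[k]]$probability,
                 sort(phi2[k, ], decreasing = TRUE)[1:10],
                 ignore_attr = TRUE)
  }
  expect_equal(sum(s2$intensity), 1, tolerance = 1e-9)
  # K = 1: intensity is exactly 1
  m1 <- lda_model(matrix(1 / 4, 1, 4), matrix(1, 3, 1))
  expect_equal(summarize_topics(m1)$intensity, 1)
})

test_that("token_share intensity uses final assignment counts", {
  bow <- tiny_bow()
  fit <- fit_lda(bow, 2, iterations = 30, burn_in = 10, seed = 3)
  s <- summarize_topics(fit, topN = 2, intensity_mode = "token_share")
  expect_equal(s$intensity, fit$n_k / sum(fit$n_k))
  expect_equal(sum(s$intensity), 1, tolerance = 1e-12)
})
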