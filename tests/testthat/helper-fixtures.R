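# Shared fixtures and independent oracles.

# Toy 14-word lexicon, two words per category; first word of each pair is
# aux-free, the Good pair's second word carries an auxiliary Happy
# attribution. Words are synthetic two-character CJK strings, stable
# across runs.
toy_lexicon_entries <- function() {
  cats <- emotion_categories()
  word <- character(14)
  for (i in seq_len(14)) {
    word[i] <- intToUtf8(c(0x4E00 + i, 0x5100 + i))
  }
  data.frame(
    word = word,
    pos_class = rep(c("noun", "verb"), 7),
    emotion = rep(cats, each = 2),
    subcategory = rep(paste0(tolower(cats), "_1"), each = 2),
    intensity = rep(c(5L, 3L), 7),
    polarity = rep(c(1L, 1L, 2L, 2L, 2L, 3L, 2L), each = 2),
    aux_emotion = c(NA, "Happy", rep(NA, 12)),
    aux_intensity = c(NA, 3L, rep(NA, 12)),
    aux_polarity = c(NA, 1L, rep(NA, 12)),
    stringsAsFactors = FALSE
  )
}

toy_lexicon <- function() emotion_lexicon(toy_lexicon_entries())

# word of a given category/slot from the toy lexicon (slot 1 or 2)
toy_word <- function(emotion, slot = 1) {
  e <- toy_lexicon_entries()
  e$word[e$emotion == emotion][slot]
}

# Independent brute-force evaluation of corpus perplexity: token-by-token
# summation of log sum_k theta[d,k] * phi[k,w], kept deliberately naive.
perplexity_oracle <- function(phi, theta, docs) {
  total_ll <- 0
  total_n <- 0
  for (d in seq_along(docs)) {
    for (w in docs[[d]]) {
      p <- 0
      for (k in seq_len(nrow(phi))) {
        p <- p + theta[d, k] * phi[k, w]
      }
      total_ll <- total_ll + log(p)
      total_n <- total_n + 1
    }
  }
  exp(-total_ll / total_n)
}

# Textbook Cohen's kappa straight from a contingency table.
kappa_oracle <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  marg_a <- rowSums(m) / n
  marg_b <- colSums(m) / n
  pe <- sum(marg_a * marg_b)
  (po - pe) / (1 - pe)
}

# Expand a contingency table into two label vectors (row = rater a).
labels_from_table <- function(m) {
  la <- character(0)
  lb <- character(0)
  rn <- rownames(m)
  cn <- colnames(m)
  if (is.null(rn)) rn <- paste0("L", seq_len(nrow(m)))
  if (is.null(cn)) cn <- paste0("L", seq_len(ncol(m)))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      k <- m[i, j]
      if (k > 0) {
        la <- c(la, rep(rn[i], k))
        lb <- c(lb, rep(cn[j], k))
      }
    }
  }
  list(a = la, b = lb)
}

# Greedy matching of fitted to planted topic rows by cosine similarity;
# returns the per-planted-topic matched cosine.
greedy_topic_cosines <- function(phi_fit, phi_true) {
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  K <- nrow(phi_true)
  sim <- matrix(0, K, nrow(phi_fit))
  for (i in seq_len(K)) {
    for (j in seq_len(nrow(phi_fit))) sim[i, j] <- cos(phi_true[i, ], phi_fit[j, ])
  }
  out <- numeric(K)
  for (step in seq_len(K)) {
    best <- which(sim == max(sim), arr.ind = TRUE)[1, ]
    out[best[1]] <- sim[best[1], best[2]]
    sim[best[1], ] <- -Inf
    sim[, best[2]] <- -Inf
  }
  out
}

# Random CJK-ish test strings mixing ideographs, ASCII and digits.
random_text <- function(len) {
  pool <- c(
    vapply(sample(0x4E00:0x4E80, 20, replace = TRUE), intToUtf8, ""),
    letters[1:6], as.character(0:9)
  )
  paste(sample(pool, len, replace = TRUE), collapse = "")
}
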