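#' Configuration for the synthetic-corpus generator
#'
#' Describes the world the generator emulates: short microblog posts over
#' a fixed vocabulary with an LDA-style document-topic mixture, emotion
#' words of known category and intensity injected at controlled rates,
#' and timestamps following a daily-volume profile with peaks. Defaults
#' describe a corpus in the style of the COVID-19 opening-up discussion:
#' the emotion mix follows the reported seven-category shares (Good 46%,
#' Happy 11%, Anger 17%, Disgust 6%, Sadness 10%, Surprise 2%, Fear 8%),
#' the date range covers 2022-11-21 to 2023-02-05, and the default daily
#' profile is flat with spikes at the policy announcement, the start of
#' the travel rush and the lunar-new-year holiday.
#'
#' @param seed Integer RNG seed; every generator output is a pure
#'   function of (config, seed).
#' @param n_docs Number of posts.
#' @param doc_length Integer (min, max) background tokens per post.
#' @param K_true Planted topic count.
#' @param V Background (neutral) vocabulary size.
#' @param topic_alpha Dirichlet concentration of document-topic mixtures.
#' @param topic_beta Dirichlet concentration of planted topic-word rows.
#' @param vocab_overlap Share of the background vocabulary common to all
#'   topics (0 = disjoint topic supports).
#' @param emotion_mix Named shares of planted dominant emotions over the
#'   7 categories; must sum to 1.
#' @param contamination Rate of off-category emotion words accompanying
#'   the injection (per injected slot).
#' @param intensity_dist Probabilities over intensity levels 1/3/5/7/9
#'   used when generating lexicon entries.
#' @param neutral_rate Share of posts receiving no emotion words (ground
#'   truth `"none"`).
#' @param date_range Character (start, end) calendar dates.
#' @param daily_profile Optional numeric vector of expected relative
#'   volumes, one per day of `date_range`; NULL builds the default
#'   flat-plus-spikes profile.
#' @param annotator_error Probability that a simulated annotator replaces
#'   the true label.
#' @param words_per_category Lexicon words generated per emotion
#'   category.
#' @param n_inject Base number of on-category emotion words injected per
#'   non-neutral post.
#' @param aux_rate Share of generated lexicon words carrying an auxiliary
#'   emotion.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_docs = 1000L,
                             doc_length = c(10L, 40L),
                             K_true = 3L,
                             V = 300L,
                             topic_alpha = 0.3,
                             topic_beta = 0.1,
                             vocab_overlap = 0,
                             emotion_mix = c(Good = 0.46, Happy = 0.11,
                                             Anger = 0.17, Disgust = 0.06,
                                             Sadness = 0.10, Surprise = 0.02,
                                             Fear = 0.08),
                             contamination = 0.05,
                             intensity_dist = c(`1` = 0.10, `3` = 0.25,
                                                `5` = 0.30, `7` = 0.25,
                                                `9` = 0.10),
                             neutral_rate = 0.05,
                             date_range = c("2022-11-21", "2023-02-05"),
                             daily_profile = NULL,
                             annotator_error = 0.10,
                             words_per_category = 20L,
                             n_inject = 3L,
                             aux_rate = 0.15) {
  cats <- emotion_categories()
  emotion_mix <- emotion_mix[cats]
  if (anyNA(emotion_mix) || abs(sum(emotion_mix) - 1) > 1e-9) {
    stop("emotion_mix must cover the 7 categories and sum to 1",
         call. = FALSE)
  }
  rates <- c(vocab_overlap = vocab_overlap, contamination = contamination,
             neutral_rate = neutral_rate, annotator_error = annotator_error,
             aux_rate = aux_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "),
         call. = FALSE)
  }
  doc_length <- as.integer(doc_length)
  if (length(doc_length) != 2 || doc_length[1] > doc_length[2] ||
      doc_length[1] < 1) {
    stop("doc_length must be (min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  if (abs(sum(intensity_dist) - 1) > 1e-9 || length(intensity_dist) != 5) {
    stop("intensity_dist must be 5 probabilities over {1,3,5,7,9} summing to 1",
         call. = FALSE)
  }
  dates <- as.Date(date_range)
  if (anyNA(dates) || dates[1] > dates[2]) {
    stop("invalid date_range", call. = FALSE)
  }
  days <- seq(dates[1], dates[2], by = "day")
  if (is.null(daily_profile)) {
    daily_profile <- default_daily_profile(days)
  }
  if (length(daily_profile) != length(days) || any(daily_profile < 0) ||
      sum(daily_profile) <= 0) {
    stop("daily_profile must be non-negative with one value per day",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_docs = as.integer(n_docs),
         doc_length = doc_length, K_true = as.integer(K_true),
         V = as.integer(V), topic_alpha = topic_alpha,
         topic_beta = topic_beta, vocab_overlap = vocab_overlap,
         emotion_mix = emotion_mix, contamination = contamination,
         intensity_dist = intensity_dist, neutral_rate = neutral_rate,
         days = days, daily_profile = as.numeric(daily_profile),
         annotator_error = annotator_error,
         words_per_category = as.integer(words_per_category),
         n_inject = as.integer(n_inject), aux_rate = aux_rate),
    class = "generator_config"
  )
}

# Flat baseline with three spike days, qualitatively emulating posting
# peaks around a policy announcement, the start of the travel rush and
# the holiday itself. Spikes that fall outside the range are dropped.
default_daily_profile <- function(days) {
  profile <- rep(1, length(days))
  spikes <- as.Date(c("2022-12-07", "2023-01-07", "2023-01-22"))
  hit <- match(spikes, days)
  profile[hit[!is.na(hit)]] <- 5
  profile
}

# Deterministic unique two-character CJK strings, excluding a given set.
make_cjk_words <- function(n, exclude = character()) {
  pool <- 0x4E00:0x9FA5
  out <- character(0)
  while (length(out) < n) {
    need <- (n - length(out)) * 2L
    cand <- vapply(seq_len(need), function(i) {
      intToUtf8(sample(pool, 2, replace = TRUE))
    }, "")
    cand <- setdiff(unique(cand), c(exclude, out))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

#' Generate a synthetic affect lexicon
#'
#' `words_per_category` unique two-character CJK-style words per emotion
#' category, with intensities drawn from `intensity_dist`, polarities
#' consistent with category valence (Good/Happy positive, the four
#' negative categories negative, Surprise "both"), all seven
#' part-of-speech classes represented, and a fraction `aux_rate` of the
#' words in the second half of each category carrying an auxiliary
#' emotion. The first word of each category never carries an auxiliary
#' emotion (the corpus generator relies on at least one unambiguous word
#' per category). The result is deterministic given the config seed and
#' passes the write/load round trip.
#'
#' @param config A [generator_config()].
#' @return An [emotion_lexicon()].
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  cats <- emotion_categories()
  n <- config$words_per_category
  if (n < 1) stop("need at least one word per category", call. = FALSE)
  total <- n * 7L
  words <- make_cjk_words(total)
  valence <- c(Good = 1L, Happy = 1L, Anger = 2L, Disgust = 2L,
               Sadness = 2L, Surprise = 3L, Fear = 2L)
  levels <- intensity_levels()
  rows <- vector("list", 7)
  for (ci in seq_along(cats)) {
    cat_name <- cats[ci]
    w <- words[((ci - 1) * n + 1):(ci * n)]
    intensity <- sample(levels, n, replace = TRUE,
                        prob = config$intensity_dist)
    pos <- pos_classes()[((seq_len(n) - 1L + (ci - 1L)) %% 7L) + 1L]
    subcat <- paste0(tolower(cat_name), "_", ((seq_len(n) - 1L) %% 3L) + 1L)
    aux_emotion <- rep(NA_character_, n)
    aux_intensity <- rep(NA_integer_, n)
    aux_polarity <- rep(NA_integer_, n)
    # auxiliary emotions only on the back half, never on the first word
    eligible <- which(seq_len(n) > max(1L, n %/% 2L))
    if (length(eligible) > 0 && config$aux_rate > 0) {
      gets_aux <- eligible[runif(length(eligible)) < config$aux_rate]
      for (i in gets_aux) {
        other <- sample(setdiff(cats, cat_name), 1)
        aux_emotion[i] <- other
        aux_intensity[i] <- sample(levels, 1, prob = config$intensity_dist)
        aux_polarity[i] <- valence[[other]]
      }
    }
    rows[[ci]] <- data.frame(
      word = w, pos_class = pos, emotion = cat_name, subcategory = subcat,
      intensity = intensity, polarity = valence[[cat_name]],
      aux_emotion = aux_emotion, aux_intensity = aux_intensity,
      aux_polarity = aux_polarity, stringsAsFactors = FALSE
    )
  }
  emotion_lexicon(do.call(rbind, rows))
}

# sample() semantics safe for length-1 vectors
sample_from <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  s <- rowSums(x)
  zero <- s <= 0
  if (any(zero)) {
    x[zero, ] <- 1 / k
    s[zero] <- 1
  }
  x / s
}

# Per-category totals of an injected word multiset under the four
# accounting conventions (intensity/count x with/without aux). Used to
# certify that the planted category is a strict winner whatever scoring
# convention the classifier runs with.
injection_scores <- function(entries, rows) {
  cats <- emotion_categories()
  out <- matrix(0, nrow = 4, ncol = 7,
                dimnames = list(c("int_aux", "cnt_aux", "int_noaux",
                                  "cnt_noaux"), cats))
  for (i in rows) {
    em <- entries$emotion[i]
    inten <- entries$intensity[i]
    out["int_aux", em] <- out["int_aux", em] + inten
    out["cnt_aux", em] <- out["cnt_aux", em] + 1
    out["int_noaux", em] <- out["int_noaux", em] + inten
    out["cnt_noaux", em] <- out["cnt_noaux", em] + 1
    if (!is.na(entries$aux_emotion[i])) {
      am <- entries$aux_emotion[i]
      out["int_aux", am] <- out["int_aux", am] + entries$aux_intensity[i]
      out["cnt_aux", am] <- out["cnt_aux", am] + 1
    }
  }
  out
}

strict_winner <- function(scores, planted) {
  others <- setdiff(colnames(scores), planted)
  all(scores[, planted] > apply(scores[, others, drop = FALSE], 1, max))
}

#' Generate a synthetic microblog corpus with known ground truth
#'
#' For each post: a document-topic mixture `theta_true` is drawn from
#' `Dirichlet(topic_alpha)`; background tokens come from planted
#' topic-word distributions `phi_true` built over a neutral vocabulary
#' (disjoint from the lexicon) with the configured topic-support overlap;
#' with probability `1 - neutral_rate` the post receives a planted
#' dominant emotion drawn from `emotion_mix`, realized by injecting
#' on-category lexicon words plus off-category words at the contamination
#' rate. Injection is constructed (by adding unambiguous on-category
#' words where needed) so that the planted category is a strict winner
#' under every scoring convention of [match_emotions()]; ground truth is
#' therefore decision-rule independent. Timestamps are sampled from the
#' configured daily-volume profile. The whole corpus is a pure function
#' of the config (including its seed).
#'
#' @param config A [generator_config()].
#' @param lexicon An [emotion_lexicon()], typically from
#'   [generate_lexicon()] with the same config.
#' @return List of class `synthetic_corpus`: `posts` (tibble `post_id`,
#'   `timestamp`, `text`), `tokens` (list of planted token vectors),
#'   `truth` (tibble `post_id`, `emotion`), `theta_true` (n_docs x
#'   K_true), `phi_true` (K_true x V), `vocabulary` (background words,
#'   needed as `user_dict` for exact re-segmentation), `lexicon`,
#'   `config`.
#' @export
generate_corpus <- function(config, lexicon) {
  stopifnot(inherits(config, "generator_config"),
            inherits(lexicon, "emotion_lexicon"))
  set.seed(config$seed)
  cats <- emotion_categories()
  K <- config$K_true
  V <- config$V
  n <- config$n_docs

  vocab <- make_cjk_words(V, exclude = lexicon$vocabulary)

  # planted topic-word rows over (possibly overlapping) supports
  n_shared <- round(config$vocab_overlap * V)
  shared <- seq_len(n_shared)
  rest <- setdiff(seq_len(V), shared)
  part <- split(rest, rep(seq_len(K), length.out = length(rest)))
  phi_true <- matrix(0, K, V)
  for (k in seq_len(K)) {
    support <- sort(c(shared, part[[k]]))
    w <- rgamma(length(support), shape = config$topic_beta)
    if (sum(w) <= 0) w <- rep(1, length(support))
    phi_true[k, support] <- w / sum(w)
  }

  theta_true <- rdirichlet(n, rep(config$topic_alpha, K))

  entries <- lexicon$entries
  # unambiguous words: no auxiliary emotion attached
  plain_by_cat <- lapply(cats, function(c) {
    which(entries$emotion == c & is.na(entries$aux_emotion))
  })
  names(plain_by_cat) <- cats
  any_by_cat <- lapply(cats, function(c) which(entries$emotion == c))
  names(any_by_cat) <- cats
  if (any(lengths(plain_by_cat) == 0)) {
    stop("lexicon must contain at least one aux-free word per category",
         call. = FALSE)
  }

  is_neutral <- runif(n) < config$neutral_rate
  planted <- rep("none", n)
  n_emo <- sum(!is_neutral)
  if (n_emo > 0) {
    planted[!is_neutral] <- sample(cats, n_emo, replace = TRUE,
                                   prob = config$emotion_mix)
  }

  day_idx <- sample(seq_along(config$days), n, replace = TRUE,
                    prob = config$daily_profile)
  secs <- floor(runif(n, 0, 86400))
  timestamps <- format(as.POSIXct(config$days[day_idx], tz = "UTC") + secs,
                       "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

  doc_lens <- sample(seq(config$doc_length[1], config$doc_length[2]),
                     n, replace = TRUE)

  tokens <- vector("list", n)
  texts <- character(n)
  for (d in seq_len(n)) {
    L <- doc_lens[d]
    z <- sample.int(K, L, replace = TRUE, prob = theta_true[d, ])
    bg <- integer(L)
    for (k in unique(z)) {
      sel <- z == k
      bg[sel] <- sample.int(V, sum(sel), replace = TRUE,
                            prob = phi_true[k, ])
    }
    toks <- vocab[bg]
    if (planted[d] != "none") {
      e <- planted[d]
      inj <- sample_from(any_by_cat[[e]], config$n_inject, replace = TRUE)
      n_contam <- rbinom(1, config$n_inject, config$contamination)
      if (n_contam > 0) {
        other_cats <- sample(setdiff(cats, e), n_contam, replace = TRUE)
        contam <- vapply(other_cats, function(c) {
          sample_from(any_by_cat[[c]], 1)
        }, 0L)
        inj <- c(inj, contam)
      }
      # certify a strict winner under all four scoring conventions,
      # topping up with unambiguous on-category words if needed
      guard <- 0L
      while (!strict_winner(injection_scores(entries, inj), e)) {
        inj <- c(inj, sample_from(plain_by_cat[[e]], 1))
        guard <- guard + 1L
        if (guard > 1000L) stop("injection failed to converge")
      }
      toks <- c(toks, entries$word[inj])
    }
    toks <- toks[sample.int(length(toks))]
    tokens[[d]] <- toks
    texts[d] <- paste(toks, collapse = "")
  }

  ids <- sprintf("post_%05d", seq_len(n))
  structure(
    list(
      posts = tibble::tibble(post_id = ids, timestamp = timestamps,
                             text = texts),
      tokens = tokens,
      truth = tibble::tibble(post_id = ids, emotion = planted),
      theta_true = theta_true,
      phi_true = phi_true,
      vocabulary = vocab,
      lexicon = lexicon,
      config = config
    ),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d posts, K_true = %d, V = %d\n",
              nrow(x$posts), x$config$K_true, x$config$V))
  invisible(x)
}

#' Simulate two independent annotators
#'
#' Each annotator copies the true label and, independently with
#' probability `annotator_error`, replaces it by a uniformly random
#' *different* label from the label set. With `annotator_error = 0` both
#' annotators reproduce the truth exactly.
#'
#' @param truth Character vector of true labels.
#' @param annotator_error Replacement probability in \[0, 1\].
#' @param seed Integer RNG seed.
#' @param labels Label set to draw replacements from; defaults to the
#'   seven emotion categories.
#' @return List with character vectors `a` and `b`.
#' @export
generate_annotations <- function(truth, annotator_error, seed = 1L,
                                 labels = emotion_categories()) {
  stopifnot(annotator_error >= 0, annotator_error <= 1)
  truth <- as.character(truth)
  set.seed(seed)
  corrupt <- function(x) {
    flip <- runif(length(x)) < annotator_error
    for (i in which(flip)) {
      pool <- setdiff(labels, x[i])
      if (length(pool) > 0) x[i] <- sample(pool, 1)
    }
    x
  }
  list(a = corrupt(truth), b = corrupt(truth))
}
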