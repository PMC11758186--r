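#' Build a bag-of-words corpus
#'
#' Maps token lists onto an indexed vocabulary. When no vocabulary is
#' supplied it is the byte-order-sorted set of observed tokens (so the
#' mapping is locale-independent and deterministic). Tokens outside a
#' supplied vocabulary are dropped.
#'
#' @param docs List of character token vectors, or a tibble with a
#'   `tokens` list-column.
#' @param vocabulary Optional character vector fixing the vocabulary.
#' @return Object of class `bow_corpus`: `vocabulary`, `docs` (list of
#'   1-based word-index vectors), `M`, `N_d`, `V`.
#' @export
make_bow <- function(docs, vocabulary = NULL) {
  if (is.data.frame(docs)) docs <- docs$tokens
  if (is.null(vocabulary)) {
    toks <- unlist(docs, use.names = FALSE)
    vocabulary <- if (is.null(toks)) character(0) else {
      sort(unique(toks), method = "radix")
    }
  }
  idx <- lapply(docs, function(t) {
    i <- match(t, vocabulary)
    as.integer(i[!is.na(i)])
  })
  structure(
    list(vocabulary = vocabulary, docs = idx, M = length(idx),
         N_d = lengths(idx), V = length(vocabulary)),
    class = "bow_corpus"
  )
}

#' Construct an LDA model object from explicit matrices
#'
#' Mainly useful for evaluating [perplexity()] or [summarize_topics()] on
#' hand-specified topic-word (`phi`) and document-topic (`theta`)
#' matrices. Rows of both must be probability distributions.
#'
#' @param phi K x V topic-word matrix.
#' @param theta M x K document-topic matrix.
#' @param ... Further fields stored on the object (e.g. `z`, counts).
#' @return Object of class `lda_model`.
#' @export
lda_model <- function(phi, theta, ...) {
  phi <- as.matrix(phi)
  theta <- as.matrix(theta)
  stopifnot(ncol(theta) == nrow(phi))
  check_rows <- function(m, what) {
    if (nrow(m) > 0 && any(abs(rowSums(m) - 1) > 1e-9)) {
      stop(what, " rows must each sum to 1", call. = FALSE)
    }
  }
  check_rows(phi, "phi")
  check_rows(theta, "theta")
  structure(
    c(list(K = nrow(phi), phi = phi, theta = theta), list(...)),
    class = "lda_model"
  )
}

#' Fit latent Dirichlet allocation by collapsed Gibbs sampling
#'
#' Standard collapsed Gibbs sampling with conditional
#' \deqn{P(z_i = k \mid z_{-i}, w) \propto (n_{d,k}^{-i} + \alpha)
#'   \frac{n_{k,w_i}^{-i} + \beta}{n_k^{-i} + V\beta}.}
#' Topic-word (`phi`) and document-topic (`theta`) matrices are
#' posterior-mean estimates averaged over every post-burn-in sweep:
#' `phi[k,w] = (n_kw + beta) / (n_k + V beta)`,
#' `theta[d,k] = (n_dk + alpha) / (N_d + K alpha)`. Identical seed and
#' configuration give a bit-identical model.
#'
#' @param corpus A [make_bow()] corpus.
#' @param K Number of topics (>= 1).
#' @param alpha Document-topic concentration; default `50 / K`.
#' @param beta Topic-word concentration; default 0.01.
#' @param iterations Total Gibbs sweeps (default 1000).
#' @param burn_in Sweeps discarded before averaging (default 200;
#'   `iterations > burn_in >= 0`).
#' @param seed Integer RNG seed.
#' @param check_counts Verify count conservation after every sweep and
#'   record the result (default TRUE; cheap).
#' @return Object of class `lda_model` with fields `K`, `alpha`, `beta`,
#'   `phi` (K x V, columns named by vocabulary), `theta` (M x K), `z`
#'   (list of 1-based per-token topic assignments from the final sweep),
#'   final count matrices `n_dk`, `n_kw`, `n_k`, `counts_conserved`
#'   (logical, one per sweep), `seed`, `iterations`, `burn_in`,
#'   `vocabulary`.
#' @export
fit_lda <- function(corpus, K, alpha = 50 / K, beta = 0.01,
                    iterations = 1000L, burn_in = 200L, seed = 1L,
                    check_counts = TRUE) {
  stopifnot(inherits(corpus, "bow_corpus"))
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (corpus$M < 1 || sum(corpus$N_d) == 0) {
    stop("corpus is empty", call. = FALSE)
  }
  stopifnot(iterations > burn_in, burn_in >= 0, alpha > 0, beta > 0)
  docs0 <- lapply(corpus$docs, function(d) d - 1L)
  set.seed(seed)
  res <- gibbs_lda_cpp(docs0, corpus$V, as.integer(K), alpha, beta,
                       as.integer(iterations), as.integer(burn_in),
                       isTRUE(check_counts))
  phi <- res$phi
  colnames(phi) <- corpus$vocabulary
  structure(
    list(K = as.integer(K), alpha = alpha, beta = beta,
         phi = phi, theta = res$theta, z = res$z,
         n_dk = res$n_dk, n_kw = res$n_kw, n_k = res$n_k,
         counts_conserved = if (isTRUE(check_counts)) res$counts_conserved else NULL,
         seed = as.integer(seed), iterations = as.integer(iterations),
         burn_in = as.integer(burn_in), vocabulary = corpus$vocabulary),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> K = %d, V = %d, M = %d\n",
              x$K, ncol(x$phi), nrow(x$theta)))
  invisible(x)
}

#' Corpus perplexity of a fitted model
#'
#' Per-document log-likelihood under the mixture
#' \eqn{\log p(w_d) = \sum_i \log \sum_k \theta_{d,k} \phi_{k,w_i}},
#' aggregated as
#' \deqn{\mathrm{perplexity} = \exp\!\left(-\frac{\sum_d \log p(w_d)}
#'   {\sum_d N_d}\right).}
#' Lower is better; the exponent (the negative mean per-token
#' log-likelihood) is additionally returned as `log_perplexity`, since a
#' log-scale value is what topic-modelling toolkits often print.
#'
#' @param model An `lda_model` (fitted or constructed via [lda_model()]).
#' @param corpus A [make_bow()] corpus over the same vocabulary.
#' @return List with `perplexity` (>= 1 for any proper model) and
#'   `log_perplexity`.
#' @export
perplexity <- function(model, corpus) {
  stopifnot(inherits(corpus, "bow_corpus"))
  if (ncol(model$phi) != corpus$V) {
    stop("model and corpus vocabulary sizes differ", call. = FALSE)
  }
  P <- model$theta %*% model$phi # M x V token probabilities
  ll <- 0
  ntot <- 0L
  for (d in seq_len(corpus$M)) {
    wd <- corpus$docs[[d]]
    if (length(wd) == 0) next
    pd <- P[d, wd]
    if (any(pd <= 0)) {
      stop("zero-probability token under the model (document ", d, ")",
           call. = FALSE)
    }
    ll <- ll + sum(log(pd))
    ntot <- ntot + length(wd)
  }
  lp <- -ll / ntot
  list(perplexity = exp(lp), log_perplexity = lp)
}

#' UMass topic coherence
#'
#' For each topic take the `topN` highest-probability words
#' \eqn{w_1, \dots, w_N} (rank order) and score
#' \deqn{\sum_{i=2}^{N}\sum_{j<i} \log \frac{D(w_i, w_j) + 1}{D(w_j)},}
#' where \eqn{D} counts corpus documents containing the word(s); the
#' reported coherence is the mean over topics. The metric depends only on
#' document co-occurrence, so it is fully determined by the corpus with
#' no external window or embedding choices. Pairs whose conditioning word
#' never occurs (`D = 0`) are excluded with a warning.
#'
#' @param model An `lda_model`.
#' @param corpus A [make_bow()] corpus over the same vocabulary.
#' @param topN Number of top words per topic (default 10, >= 2).
#' @return Mean coherence (a non-positive number in practice; higher,
#'   i.e. closer to 0, is more coherent).
#' @export
coherence_umass <- function(model, corpus, topN = 10L) {
  stopifnot(inherits(corpus, "bow_corpus"), topN >= 2)
  V <- corpus$V
  # document frequency of every word
  D <- integer(V)
  per_doc <- lapply(corpus$docs, unique)
  for (u in per_doc) D[u] <- D[u] + 1L
  scores <- numeric(model$K)
  warned <- FALSE
  for (k in seq_len(model$K)) {
    top <- top_word_indices(model$phi[k, ], topN)
    m <- length(top)
    # co-document counts restricted to the top words
    inc <- vapply(per_doc, function(u) top %in% u, logical(m))
    if (m == 1) inc <- matrix(inc, nrow = 1)
    co <- inc %*% t(inc) # m x m co-occurrence document counts
    s <- 0
    for (i in seq_len(m)[-1]) {
      for (j in seq_len(i - 1)) {
        if (D[top[j]] == 0) {
          warned <- TRUE
          next
        }
        s <- s + log((co[i, j] + 1) / D[top[j]])
      }
    }
    scores[k] <- s
  }
  if (warned) warning("pairs with never-occurring conditioning word excluded")
  mean(scores)
}

# Indices of the topN largest entries; ties broken by index for
# determinism.
top_word_indices <- function(p, topN) {
  ord <- order(-p, seq_along(p), method = "radix")
  ord[seq_len(min(topN, length(p)))]
}

#' Sweep the number of topics
#'
#' Fits one model per K, scoring each by training perplexity
#' ([perplexity()]) and UMass coherence ([coherence_umass()]), and
#' applies [select_k()]. Each fit is re-seeded with `seed + K` so the
#' fits are mutually independent yet the whole sweep is deterministic.
#'
#' @param corpus A [make_bow()] corpus.
#' @param k_range Integer vector of topic counts (e.g. `1:15`).
#' @param alpha Document-topic concentration, or NULL for the per-K
#'   default `50 / K`.
#' @param beta Topic-word concentration (default 0.01).
#' @param iterations,burn_in Gibbs sweep budget per fit.
#' @param seed Base RNG seed.
#' @param topN Top words per topic for coherence (default 10).
#' @param keep_models Also return the fitted models (default FALSE).
#' @return Object of class `ksweep_result`: `records` (tibble `K`,
#'   `perplexity`, `log_perplexity`, `coherence`), `selected_K`,
#'   `selection_rule`, and optionally `models`.
#' @export
sweep_k <- function(corpus, k_range, alpha = NULL, beta = 0.01,
                    iterations = 500L, burn_in = 100L, seed = 1L,
                    topN = 10L, keep_models = FALSE) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop("k_range is empty", call. = FALSE)
  recs <- vector("list", length(k_range))
  models <- if (keep_models) vector("list", length(k_range)) else NULL
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    a <- if (is.null(alpha)) 50 / K else alpha
    fit <- fit_lda(corpus, K, alpha = a, beta = beta,
                   iterations = iterations, burn_in = burn_in,
                   seed = seed + K, check_counts = FALSE)
    pp <- perplexity(fit, corpus)
    coh <- if (K >= 1) coherence_umass(fit, corpus, topN = topN) else NA_real_
    recs[[i]] <- tibble::tibble(
      K = K, perplexity = pp$perplexity,
      log_perplexity = pp$log_perplexity, coherence = coh
    )
    if (keep_models) models[[i]] <- fit
  }
  records <- do.call(rbind, recs)
  structure(
    list(records = records, selected_K = select_k(records),
         selection_rule = "coherence local maximum with lowest perplexity",
         models = models),
    class = "ksweep_result"
  )
}

#' @export
print.ksweep_result <- function(x, ...) {
  cat(sprintf("<ksweep_result> K in [%d, %d]; selected K = %d\n",
              min(x$records$K), max(x$records$K), x$selected_K))
  print(x$records)
  invisible(x)
}

#' Select the operating number of topics
#'
#' Operationalizes the "peak coherence with slowly declining perplexity"
#' principle. Coherence leads: among the K whose coherence is an interior
#' local maximum of the coherence-vs-K curve (strictly greater than both
#' neighbours), choose the most coherent peak; perplexity arbitrates only
#' between equally coherent peaks (lower wins), and remaining ties
#' resolve to the smallest K. When no interior local maximum exists
#' (e.g. a monotone curve or fewer than three candidate K) the global
#' coherence maximum is chosen. Training perplexity keeps improving as K
#' grows, so making it primary would systematically favour the largest
#' spurious peak; treating it as a tie-break keeps the rule faithful to
#' selecting the coherence peak while still preferring the
#' better-fitting model when coherence cannot discriminate.
#'
#' @param records Data frame with columns `K`, `perplexity`, `coherence`
#'   (one row per K, any order).
#' @return Selected K (integer).
#' @export
select_k <- function(records) {
  records <- records[order(records$K), , drop = FALSE]
  n <- nrow(records)
  if (n == 0) stop("no records", call. = FALSE)
  if (n <= 2) {
    i <- which(records$coherence == max(records$coherence))[1]
    return(records$K[i])
  }
  coh <- records$coherence
  peaks <- which(
    seq_len(n) > 1 & seq_len(n) < n &
      coh > c(Inf, coh[-n]) & coh > c(coh[-1], Inf)
  )
  if (length(peaks) == 0) {
    i <- which(coh == max(coh))[1]
    return(records$K[i])
  }
  best <- peaks[order(-coh[peaks], records$perplexity[peaks],
                      records$K[peaks])][1]
  records$K[best]
}

#' Summarize fitted topics
#'
#' Per topic, the `topN` highest-probability keywords with their
#' probabilities (the layout of a topic-keyword table), plus a topic
#' intensity: by default the mean over documents of the document-topic
#' weight `theta[, k]` (the relative share of the topic in the corpus;
#' the intensities sum to 1). `intensity_mode = "token_share"` instead
#' uses the share of token assignments per topic from the final Gibbs
#' state.
#'
#' @param model An `lda_model`.
#' @param topN Keywords per topic (default 10).
#' @param intensity_mode `"mean_theta"` (default) or `"token_share"`.
#' @return Object of class `topic_summary`: `topics` (list of tibbles
#'   `word`, `probability`, non-increasing), `intensity` (numeric, sums
#'   to 1).
#' @export
summarize_topics <- function(model, topN = 10L,
                             intensity_mode = c("mean_theta", "token_share")) {
  intensity_mode <- match.arg(intensity_mode)
  stopifnot(topN >= 1)
  vocab <- colnames(model$phi)
  if (is.null(vocab)) vocab <- as.character(seq_len(ncol(model$phi)))
  topics <- lapply(seq_len(model$K), function(k) {
    idx <- top_word_indices(model$phi[k, ], topN)
    tibble::tibble(word = vocab[idx], probability = model$phi[k, idx])
  })
  intensity <- if (intensity_mode == "mean_theta") {
    colMeans(model$theta)
  } else {
    if (is.null(model$n_k)) {
      stop("token_share intensity requires a fitted model", call. = FALSE)
    }
    model$n_k / sum(model$n_k)
  }
  structure(list(topics = topics, intensity = as.numeric(intensity),
                 intensity_mode = intensity_mode),
            class = "topic_summary")
}
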