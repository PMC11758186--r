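#' Confusion matrix of two label vectors
#'
#' @param reference,prediction Equal-length label vectors.
#' @param labels Optional label set fixing row/column order; default is
#'   the sorted union of observed labels.
#' @return Square integer matrix, rows = reference, columns = prediction.
#' @export
confusion_matrix <- function(reference, prediction, labels = NULL) {
  reference <- as.character(reference)
  prediction <- as.character(prediction)
  if (length(reference) != length(prediction)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- sort(unique(c(reference, prediction)), method = "radix")
  }
  bad <- setdiff(unique(c(reference, prediction)), labels)
  if (length(bad) > 0) {
    stop("labels outside the declared label set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- table(factor(reference, levels = labels),
             factor(prediction, levels = labels))
  mat <- matrix(as.integer(m), nrow = length(labels),
                dimnames = list(reference = labels, prediction = labels))
  mat
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)}
#' with \eqn{p_o} the observed agreement fraction and
#' \eqn{p_e = \sum_c m_a(c)\, m_b(c)} the chance agreement from the two
#' raters' marginals. The result is banded following the convention:
#' 0.61-0.80 good, 0.81-1 excellent consistency; anything below 0.61 is
#' reported as `"below_good"` without finer subdivision. When both raters
#' assign a single identical label throughout, \eqn{p_e = 1} and kappa is
#' undefined: the report flags `degenerate = TRUE` with `po = 1` and
#' `kappa = NA`.
#'
#' @param labels_a,labels_b Equal-length label vectors (rater A, rater
#'   B), or omit `labels_b` and pass a square contingency table/matrix as
#'   `labels_a` (rows = rater A, columns = rater B).
#' @return List of class `agreement_report`: `kappa`, `band`, `po`,
#'   `pe`, `n`, `degenerate`.
#' @export
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 15), 2, 2))$kappa # 0.4
cohen_kappa <- function(labels_a, labels_b = NULL) {
  if (is.null(labels_b)) {
    m <- as.matrix(labels_a)
    if (nrow(m) != ncol(m)) stop("contingency table must be square",
                                 call. = FALSE)
  } else {
    m <- confusion_matrix(labels_a, labels_b)
  }
  n <- sum(m)
  if (n < 1) stop("need at least one paired item", call. = FALSE)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    return(structure(
      list(kappa = NA_real_, band = "degenerate", po = po, pe = pe,
           n = n, degenerate = TRUE),
      class = "agreement_report"
    ))
  }
  kappa <- (po - pe) / (1 - pe)
  band <- if (kappa >= 0.81) "excellent" else if (kappa >= 0.61) "good" else "below_good"
  structure(
    list(kappa = kappa, band = band, po = po, pe = pe, n = n,
         degenerate = FALSE),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> kappa = %s (%s), po = %.4f, pe = %.4f, n = %d\n",
              format(x$kappa, digits = 4), x$band, x$po, x$pe, x$n))
  invisible(x)
}

#' Multi-class precision, recall, F1 and accuracy
#'
#' One-vs-rest counts per class; `macro` averaging (default) is the
#' unweighted mean over classes observed in either vector, `micro` pools
#' the counts (for single-label classification micro precision, recall
#' and F1 all equal accuracy). Per-class metrics with an empty
#' denominator are defined as 0.
#'
#' @param reference Gold labels.
#' @param prediction Predicted labels, same length.
#' @param averaging `"macro"` or `"micro"`.
#' @return List of class `validity_report`: `accuracy`, `precision`,
#'   `recall`, `f1` (under the chosen averaging), `averaging`,
#'   `per_class` (tibble with class-wise counts and metrics).
#' @export
prf_multiclass <- function(reference, prediction,
                           averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  reference <- as.character(reference)
  prediction <- as.character(prediction)
  if (length(reference) != length(prediction)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (length(reference) == 0) stop("need at least one item", call. = FALSE)
  classes <- sort(unique(c(reference, prediction)), method = "radix")
  tp <- fp <- fn <- integer(length(classes))
  for (i in seq_along(classes)) {
    c <- classes[i]
    tp[i] <- sum(reference == c & prediction == c)
    fp[i] <- sum(reference != c & prediction == c)
    fn[i] <- sum(reference == c & prediction != c)
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn) # = 2PR/(P+R), exact on counts
  per_class <- tibble::tibble(
    class = classes, tp = tp, fp = fp, fn = fn,
    precision = prec, recall = rec, f1 = f1
  )
  accuracy <- mean(reference == prediction)
  if (averaging == "macro") {
    precision <- mean(prec)
    recall <- mean(rec)
    f1_avg <- mean(f1)
  } else {
    precision <- safe_div(sum(tp), sum(tp) + sum(fp))
    recall <- safe_div(sum(tp), sum(tp) + sum(fn))
    f1_avg <- safe_div(2 * sum(tp), 2 * sum(tp) + sum(fp) + sum(fn))
  }
  structure(
    list(accuracy = accuracy, precision = precision, recall = recall,
         f1 = f1_avg, averaging = averaging, per_class = per_class),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf(
    "<validity_report> accuracy = %.4f, %s precision = %.4f, recall = %.4f, F1 = %.4f\n",
    x$accuracy, x$averaging, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Check validity metrics against thresholds
#'
#' Flags whether each headline metric reaches its threshold (inclusive),
#' following the "excellent validity" convention of accuracy >= 0.85,
#' recall >= 0.80 and F1 >= 0.80.
#'
#' @param report A `validity_report` (or list with `accuracy`, `recall`,
#'   `f1`).
#' @param thresholds Named list of thresholds.
#' @return Named logical vector `accuracy`, `recall`, `f1` plus an
#'   attribute-free `all_pass` entry.
#' @export
validity_gate <- function(report,
                          thresholds = list(accuracy = 0.85, recall = 0.80,
                                            f1 = 0.80)) {
  flags <- c(
    accuracy = report$accuracy >= thresholds$accuracy,
    recall = report$recall >= thresholds$recall,
    f1 = report$f1 >= thresholds$f1
  )
  c(flags, all_pass = all(flags))
}

#' Agreement between two topic-to-theme mappings
#'
#' Treats topics as items and theme labels as categories and delegates to
#' [cohen_kappa()], supporting the reliability check of a manual
#' clustering of topics into higher-level themes by two independent
#' coders.
#'
#' @param map_a,map_b Named vectors (topic id -> theme label) over the
#'   same topic set.
#' @return An `agreement_report`.
#' @export
theme_mapping_agreement <- function(map_a, map_b) {
  if (is.null(names(map_a)) || is.null(names(map_b))) {
    stop("mappings must be named by topic", call. = FALSE)
  }
  if (!setequal(names(map_a), names(map_b)) ||
      length(map_a) != length(map_b)) {
    stop("mappings must cover the same topic set", call. = FALSE)
  }
  topics <- names(map_a)
  cohen_kappa(as.character(map_a[topics]), as.character(map_b[topics]))
}
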