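#' Cosine similarity between two vectors
#'
#' `u . v / (|u| |v|)`. Zero vectors have no direction, so they raise an
#' error rather than silently returning 0.
#'
#' @param u,v numeric vectors of equal length.
#' @return a number in `[-1, 1]`.
#' @examples
#' cosine_sim(c(1, 0), c(1, 1))  # sqrt(2)/2
#' @export
cosine_sim <- function(u, v) {
  if (length(u) != length(v))
    stop_fmt("vectors have different lengths (%d vs %d)", length(u), length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop_fmt("cosine similarity of a zero vector is undefined")
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Summarize a sample of similarity scores
#'
#' Mean, sample standard deviation (n-1 denominator) and the normal-theory
#' 95% confidence interval `mean +/- 1.96 * sd / sqrt(n)` — the interval
#' construction conventional for large per-item score samples.
#'
#' @param values numeric vector, length at least 2.
#' @return an object of class `cosine_summary`: list with `mean`, `sd`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
summarize_scores <- function(values) {
  if (length(values) < 2L) stop_fmt("need at least 2 values to summarize")
  m <- mean(values)
  s <- stats::sd(values)
  half <- 1.96 * s / sqrt(length(values))
  structure(list(mean = m, sd = s, ci_low = m - half, ci_high = m + half,
                 n = length(values)),
            class = "cosine_summary")
}

#' Reconstruct a 95% confidence interval from summary statistics
#'
#' Applies the same `mean +/- 1.96 * sd / sqrt(n)` construction as
#' [summarize_scores()] directly to reported summary statistics.
#'
#' @param mean,sd,n summary statistics of the score sample.
#' @return numeric vector `c(ci_low, ci_high)`.
#' @examples
#' ci_from_summary(0.2343, 0.0411, 3423)
#' @export
ci_from_summary <- function(mean, sd, n) {
  half <- 1.96 * sd / sqrt(n)
  c(ci_low = mean - half, ci_high = mean + half)
}

#' @export
print.cosine_summary <- function(x, ...) {
  cat(sprintf("mean %.4f, SD %.4f, 95%% CI [%.4f, %.4f], n = %d\n",
              x$mean, x$sd, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Paired contrast between two per-item score samples
#'
#' Paired-samples t-test of `a` against `b` (paired by test item), two-sided,
#' with the paired Cohen's d effect size `mean(a - b) / sd(a - b)`. Degenerate
#' cases: if all differences are zero the contrast is null (`t = 0, p = 1,
#' d = 0`); if the differences have zero spread but a nonzero mean, `t` is
#' infinite and `p = 0`.
#'
#' @param a,b numeric vectors of equal length (n >= 2), e.g. per-item cosines
#'   of the experimental and the baseline model.
#' @return an object of class `paired_contrast`: list with `t`, `p`, `d`,
#'   `df`, `mean_diff`, and `summary_a` / `summary_b` ([summarize_scores()]
#'   of each sample).
#' @export
paired_contrast <- function(a, b) {
  if (length(a) != length(b))
    stop_fmt("paired samples must have equal length (%d vs %d)",
             length(a), length(b))
  n <- length(a)
  if (n < 2L) stop_fmt("need at least 2 pairs")
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    tt <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
    dd <- if (md == 0) 0 else sign(md) * Inf
  } else {
    tt <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE)
    dd <- md / sdd
  }
  structure(list(t = tt, p = p, d = dd, df = n - 1L, mean_diff = md,
                 summary_a = summarize_scores(a), summary_b = summarize_scores(b)),
            class = "paired_contrast")
}

#' @export
print.paired_contrast <- function(x, ...) {
  cat(sprintf("paired contrast: t(%d) = %.4f, p = %.4g, d = %.4f\n",
              x$df, x$t, x$p, x$d))
  invisible(x)
}

#' McNemar test on paired classifier correctness
#'
#' Standard chi-square McNemar test on the discordant cells of two paired
#' classifiers: with `b` = items only the first classifier got right and
#' `c` = items only the second got right, `chi2 = (b - c)^2 / (b + c)` with
#' one degree of freedom. Applied without continuity correction by default;
#' `correct = TRUE` applies the Edwards correction.
#'
#' @param correct_model,correct_baseline logical vectors of equal length:
#'   per-item correctness of the two classifiers.
#' @param correct apply the continuity correction.
#' @return an object of class `mcnemar_result`: list with `chi2`, `p`, `b`,
#'   `c`, and `degenerate` (`TRUE` when `b + c = 0`, in which case `chi2 = 0,
#'   p = 1`).
#' @export
mcnemar_chisq <- function(correct_model, correct_baseline, correct = FALSE) {
  if (length(correct_model) != length(correct_baseline))
    stop_fmt("paired correctness vectors must have equal length")
  stopifnot(is.logical(correct_model), is.logical(correct_baseline))
  b <- sum(correct_model & !correct_baseline)
  cc <- sum(!correct_model & correct_baseline)
  if (b + cc == 0L) {
    warning("no discordant pairs; McNemar statistic undefined, reporting chi2 = 0, p = 1")
    return(structure(list(chi2 = 0, p = 1, b = b, c = cc, degenerate = TRUE),
                     class = "mcnemar_result"))
  }
  num <- if (correct) (abs(b - cc) - 1)^2 else (b - cc)^2
  chi2 <- max(0, num) / (b + cc)
  structure(list(chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 b = b, c = cc, degenerate = FALSE),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar: chi2(1) = %.4f, p = %.4g (b = %d, c = %d)\n",
              x$chi2, x$p, x$b, x$c))
  invisible(x)
}

#' Multiclass classification metrics
#'
#' Accuracy, support-weighted precision, support-weighted F1 and per-class
#' accuracy (= per-class recall). Weighted averages use class supports in the
#' true labels as weights; a class that is never predicted contributes
#' precision 0. Support-weighted recall equals accuracy, so it is not
#' reported separately.
#'
#' @param true_labels,predicted_labels vectors of equal length with values in
#'   `classes`.
#' @param classes the class inventory (fixes the order of
#'   `per_class_accuracy`).
#' @return an object of class `class_metrics`: list with `accuracy`,
#'   `weighted_precision`, `weighted_f1`, `per_class_accuracy` (named vector,
#'   `NA` for classes with no support), `support` (named vector).
#' @export
classification_metrics <- function(true_labels, predicted_labels, classes) {
  if (!length(true_labels)) stop_fmt("empty label vectors")
  if (length(true_labels) != length(predicted_labels))
    stop_fmt("label vectors must have equal length")
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  classes <- as.character(classes)
  if (!all(true_labels %in% classes) || !all(predicted_labels %in% classes))
    stop_fmt("labels outside the declared class inventory")
  n <- length(true_labels)
  support <- prec <- rec <- f1 <- stats::setNames(numeric(length(classes)), classes)
  for (k in classes) {
    tp <- sum(true_labels == k & predicted_labels == k)
    support[k] <- sum(true_labels == k)
    pred_k <- sum(predicted_labels == k)
    prec[k] <- if (pred_k > 0) tp / pred_k else 0
    rec[k] <- if (support[k] > 0) tp / support[k] else NA_real_
    f1[k] <- if (prec[k] + max(rec[k], 0, na.rm = TRUE) > 0 && support[k] > 0)
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  w <- support / n
  structure(list(accuracy = mean(true_labels == predicted_labels),
                 weighted_precision = sum(w * prec),
                 weighted_f1 = sum(w * ifelse(is.na(f1), 0, f1)),
                 per_class_accuracy = rec,
                 support = support),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f, weighted precision %.4f, weighted F1 %.4f\n",
              x$accuracy, x$weighted_precision, x$weighted_f1))
  invisible(x)
}

#' Cross-language consistency of per-class accuracy
#'
#' Measures whether the same word classes are easy or hard across languages:
#' the Pearson correlation between the class-indexed accuracy vectors of
#' every unordered language pair, averaged, plus the second-order per-class
#' mean accuracy across languages. Languages whose accuracy vector has zero
#' variance carry no ranking information; their pairs are excluded and
#' flagged.
#'
#' @param per_language named list: language -> named numeric vector of
#'   per-class accuracy (identical class sets).
#' @return list with `mean_pairwise_r`, `pairwise` (data.frame lang1, lang2,
#'   r), `per_class_mean` (named vector), `excluded` (character vector of
#'   zero-variance languages).
#' @export
cross_language_consistency <- function(per_language) {
  if (length(per_language) < 2L) stop_fmt("need at least 2 languages")
  classes <- names(per_language[[1]])
  for (v in per_language)
    if (!identical(sort(names(v)), sort(classes)))
      stop_fmt("all languages must report the same class set")
  mat <- do.call(rbind, lapply(per_language, function(v) v[classes]))
  rownames(mat) <- names(per_language)
  per_class_mean <- colMeans(mat, na.rm = TRUE)
  variances <- apply(mat, 1, function(v) stats::var(v[!is.na(v)]))
  excluded <- rownames(mat)[is.na(variances) | variances == 0]
  if (length(excluded))
    warning(sprintf("zero-variance accuracy vector(s) excluded: %s",
                    paste(excluded, collapse = ", ")))
  usable <- setdiff(rownames(mat), excluded)
  pairwise <- if (length(usable) >= 2L) {
    pairs <- utils::combn(usable, 2)
    data.frame(lang1 = pairs[1, ], lang2 = pairs[2, ],
               r = apply(pairs, 2, function(pr) {
                 ok <- !is.na(mat[pr[1], ]) & !is.na(mat[pr[2], ])
                 stats::cor(mat[pr[1], ok], mat[pr[2], ok])
               }),
               stringsAsFactors = FALSE)
  } else {
    data.frame(lang1 = character(0), lang2 = character(0), r = numeric(0))
  }
  list(mean_pairwise_r = if (nrow(pairwise)) mean(pairwise$r) else NA_real_,
       pairwise = pairwise,
       per_class_mean = per_class_mean,
       excluded = excluded)
}
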