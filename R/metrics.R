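# The diagnostic-metric panel. All metrics are computed and stored as
# fractions; percent formatting happens only at the report layer. A metric
# whose denominator is empty raises a typed "undefined_metric" condition
# rather than returning 0 or NaN — small cohorts can legitimately have
# empty confusion-matrix cells, and silence there corrupts summaries.

undefined_metric <- function(metric, reason) {
  stop(errorCondition(
    sprintf("%s is undefined: %s", metric, reason),
    class = c("undefined_metric", "ggnrads_error")
  ))
}

#' Build a confusion matrix from binary calls
#'
#' Tallies TP (called positive, truly positive), FP, FN and TN from
#' parallel logical vectors.
#'
#' @param predicted logical vector of predicted calls.
#' @param truth logical vector of true labels, same length.
#' @return A `confusion_matrix` object with integer fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @seealso [confusion_counts()] to build one directly from counts,
#'   [metric_panel()] for the full panel.
#' @export
confusion_matrix <- function(predicted, truth) {
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have the same length", call. = FALSE)
  }
  if (length(predicted) == 0) stop("empty input", call. = FALSE)
  if (anyNA(predicted) || anyNA(truth)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  confusion_counts(
    tp = sum(predicted & truth),
    fp = sum(predicted & !truth),
    fn = sum(!predicted & truth),
    tn = sum(!predicted & !truth)
  )
}

#' @rdname confusion_matrix
#' @param tp,fp,fn,tn non-negative integer counts; the total must be
#'   positive.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("confusion matrix total must be > 0", call. = FALSE)
  counts <- as.integer(round(counts))
  structure(
    list(tp = counts[1], fp = counts[2], fn = counts[3], tn = counts[4]),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf(
    "Confusion matrix (n = %d)\n           truth+  truth-\n  called+  %6d  %6d\n  called-  %6d  %6d\n",
    x$tp + x$fp + x$fn + x$tn, x$tp, x$fp, x$fn, x$tn
  ))
  invisible(x)
}

cm_check <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    stop("expected a confusion_matrix", call. = FALSE)
  }
  cm
}

#' Scalar diagnostic metrics of a confusion matrix
#'
#' Standard definitions on the fraction scale:
#' * `precision(cm)` = TP / (TP + FP)
#' * `recall(cm)` = sensitivity = TP / (TP + FN)
#' * `specificity(cm)` = TN / (TN + FP)
#' * `accuracy(cm)` = (TP + TN) / (TP + FP + FN + TN)
#'
#' A zero denominator raises a condition of class `"undefined_metric"`.
#'
#' @param cm a [confusion_matrix()].
#' @return A fraction in `[0, 1]`.
#' @export
precision <- function(cm) {
  cm <- cm_check(cm)
  if (cm$tp + cm$fp == 0) undefined_metric("precision", "no positive calls (TP + FP = 0)")
  cm$tp / (cm$tp + cm$fp)
}

#' @rdname precision
#' @export
recall <- function(cm) {
  cm <- cm_check(cm)
  if (cm$tp + cm$fn == 0) undefined_metric("recall", "no positive cases (TP + FN = 0)")
  cm$tp / (cm$tp + cm$fn)
}

#' @rdname precision
#' @export
specificity <- function(cm) {
  cm <- cm_check(cm)
  if (cm$tn + cm$fp == 0) undefined_metric("specificity", "no negative cases (TN + FP = 0)")
  cm$tn / (cm$tn + cm$fp)
}

#' @rdname precision
#' @export
accuracy <- function(cm) {
  cm <- cm_check(cm)
  (cm$tp + cm$tn) / (cm$tp + cm$fp + cm$fn + cm$tn)
}

#' F-beta score
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`. `beta = 1` gives the usual
#' F1; `beta = 0.5` (the panel default) weights precision over recall,
#' attenuating the influence of false negatives in a high-prevalence
#' screening cohort.
#'
#' @param cm a [confusion_matrix()].
#' @param beta positive weight.
#' @return A fraction in `[0, 1]`.
#' @export
f_beta <- function(cm, beta = 0.5) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0) {
    stop("beta must be a positive number", call. = FALSE)
  }
  p <- precision(cm)
  r <- recall(cm)
  if (p == 0 && r == 0) {
    undefined_metric("f_beta", "precision and recall are both zero")
  }
  (1 + beta^2) * p * r / (beta^2 * p + r)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, identically the
#' Pearson correlation of the 0/1 prediction and truth indicator vectors.
#' Undefined when any marginal is empty.
#'
#' @param cm a [confusion_matrix()].
#' @return A value in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  cm <- cm_check(cm)
  m <- c(cm$tp + cm$fp, cm$tp + cm$fn, cm$tn + cm$fp, cm$tn + cm$fn)
  if (any(m == 0)) {
    undefined_metric("mcc", "a confusion-matrix marginal is zero")
  }
  (as.numeric(cm$tp) * cm$tn - as.numeric(cm$fp) * cm$fn) / sqrt(prod(as.numeric(m)))
}

#' Single-operating-point ROC AUC
#'
#' The empirical ROC area of a binary (one-threshold) classifier:
#' `(sensitivity + specificity) / 2`, which equals the Mann-Whitney
#' probability that a random positive outranks a random negative with ties
#' counted half.
#'
#' @param cm a [confusion_matrix()]; needs at least one positive and one
#'   negative case.
#' @return AUC in `[0, 1]`.
#' @export
auc_single_point <- function(cm) {
  (recall(cm) + specificity(cm)) / 2
}

#' Recall variant TP / (TP + TN)
#'
#' A reproduction-only diagnostic: the ratio of true positives to all
#' correct calls. This is **not** a valid recall — it is exposed under an
#' explicit name because published per-model "recall" rows sometimes follow
#' this ratio rather than TP / (TP + FN), and auditing such tables needs
#' the quantity by name.
#'
#' @param cm a [confusion_matrix()].
#' @return TP / (TP + TN).
#' @export
printed_recall_variant <- function(cm) {
  cm <- cm_check(cm)
  if (cm$tp + cm$tn == 0) {
    undefined_metric("printed_recall_variant", "TP + TN = 0")
  }
  cm$tp / (cm$tp + cm$tn)
}

#' Hanley-McNeil confidence interval for a single-point AUC
#'
#' Normal-approximation interval with the Hanley & McNeil (1982) standard
#' error, using the numbers of positive and negative cases in the matrix.
#' Provided for completeness when reporting single-operating-point AUCs;
#' published AUC intervals computed by other (often unstated) methods will
#' generally not match it.
#'
#' @param cm a [confusion_matrix()].
#' @param conf_level confidence level (default 0.95).
#' @return List with `auc`, `se`, `lower`, `upper` (clamped to `[0, 1]`).
#' @export
auc_ci_hanley_mcneil <- function(cm, conf_level = 0.95) {
  a <- auc_single_point(cm)
  np <- cm$tp + cm$fn
  nn <- cm$tn + cm$fp
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (np - 1) * (q1 - a^2) + (nn - 1) * (q2 - a^2)) / (np * nn))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(
    auc = a, se = se,
    lower = max(0, a - z * se), upper = min(1, a + z * se)
  )
}

#' Full diagnostic-metric panel for one confusion matrix
#'
#' Computes recall, precision, accuracy, F1, the F-beta "weighted" F score,
#' MCC, single-point AUC, and the [printed_recall_variant()] diagnostic in
#' one pass. A metric that is undefined for this matrix (empty denominator)
#' is reported as `NA` and listed in the `undefined` field instead of
#' failing the whole panel.
#'
#' @param cm a [confusion_matrix()].
#' @param beta F-beta weight for the weighted F score (default 0.5).
#' @return A `metric_panel` list: the four counts, `beta`, all metric
#'   fields on the fraction scale, and `undefined` (character vector of
#'   metric names that could not be computed).
#' @examples
#' metric_panel(confusion_counts(tp = 184, fp = 3, fn = 32, tn = 4))
#' @export
metric_panel <- function(cm, beta = 0.5) {
  cm <- cm_check(cm)
  undefined <- character()
  safely <- function(name, expr) {
    tryCatch(expr, undefined_metric = function(e) {
      undefined <<- c(undefined, name)
      NA_real_
    })
  }
  panel <- list(
    tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn, beta = beta,
    recall = safely("recall", recall(cm)),
    precision = safely("precision", precision(cm)),
    accuracy = accuracy(cm),
    f1 = safely("f1", f_beta(cm, 1)),
    f_weighted = safely("f_weighted", f_beta(cm, beta)),
    mcc = safely("mcc", mcc(cm)),
    auc = safely("auc", auc_single_point(cm)),
    printed_recall_variant = safely(
      "printed_recall_variant", printed_recall_variant(cm)
    )
  )
  panel$undefined <- undefined
  structure(panel, class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, ...) {
  cat(sprintf(
    "Metric panel (TP %d, FP %d, FN %d, TN %d; beta = %g)\n",
    x$tp, x$fp, x$fn, x$tn, x$beta
  ))
  fmt <- function(v, d = 2) if (is.na(v)) "undefined" else sprintf("%.*f", d, v)
  cat(sprintf("  recall      %s %%\n", fmt(percent(x$recall))))
  cat(sprintf("  precision   %s %%\n", fmt(percent(x$precision))))
  cat(sprintf("  accuracy    %s %%\n", fmt(percent(x$accuracy))))
  cat(sprintf("  F1          %s %%\n", fmt(percent(x$f1))))
  cat(sprintf("  F_weighted  %s %%\n", fmt(percent(x$f_weighted))))
  cat(sprintf("  MCC         %s %%\n", fmt(percent(x$mcc))))
  cat(sprintf("  AUC         %s\n", fmt(x$auc, 3)))
  invisible(x)
}
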