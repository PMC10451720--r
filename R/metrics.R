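#' Confusion counts for binary clip classification
#'
#' Aggression is the positive class (label 1) throughout.
#'
#' @param truth Integer 0/1 vector of reference labels.
#' @param estimate Integer 0/1 vector of predicted labels.
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    rlang::abort("`truth` and `estimate` must have equal length.")
  }
  if (!all(truth %in% c(0, 1)) || !all(estimate %in% c(0, 1))) {
    rlang::abort("`truth` and `estimate` must be 0/1.")
  }
  structure(list(tp = sum(truth == 1 & estimate == 1),
                 fp = sum(truth == 0 & estimate == 1),
                 fn = sum(truth == 1 & estimate == 0),
                 tn = sum(truth == 0 & estimate == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts>\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(reference = c("positive", "negative"),
                              prediction = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. A ratio with zero
#' denominator is reported as 0 with `undefined = TRUE`, so batch
#' evaluation never aborts on a degenerate split.
#'
#' @param confusion A [confusion_counts()] object, or `tp` as a count.
#' @param fp,fn,tn Counts, when `confusion` is given as `tp`.
#' @return A one-row tibble: `precision`, `recall`, `f1`, `undefined`.
#' @examples
#' precision_recall_f1(confusion_counts(c(1, 1, 0), c(1, 0, 0)))
#' precision_recall_f1(395, fp = 28, fn = 35, tn = 427)
#' @export
precision_recall_f1 <- function(confusion, fp = NULL, fn = NULL, tn = NULL) {
  if (inherits(confusion, "confusion_counts")) {
    cm <- confusion
  } else {
    cm <- list(tp = confusion, fp = fp, fn = fn, tn = tn)
  }
  undefined <- FALSE
  ratio <- function(num, den) {
    if (den <= 0) {
      undefined <<- TRUE
      0
    } else num / den
  }
  p <- ratio(cm$tp, cm$tp + cm$fp)
  r <- ratio(cm$tp, cm$tp + cm$fn)
  f1 <- ratio(2 * p * r, p + r)
  if (undefined) rlang::warn("zero denominator: undefined ratio(s) reported as 0.")
  tibble::tibble(precision = p, recall = r, f1 = f1, undefined = undefined)
}

#' ROC curve and AUC
#'
#' Sweeps the unique predicted probabilities as decision thresholds (plus
#' the degenerate all-positive / all-negative ends), producing
#' (FPR, TPR) points from (0, 0) to (1, 1); the area is integrated with the
#' trapezoidal rule. With tied scores this equals the Mann-Whitney pairwise
#' statistic with half credit for ties.
#'
#' @param truth Integer 0/1 vector; must contain both classes.
#' @param probability Numeric scores (higher = more aggressive).
#' @return A list with `roc_points` (tibble `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(truth, probability) {
  if (length(truth) != length(probability)) {
    rlang::abort("`truth` and `probability` must have equal length.")
  }
  if (!all(truth %in% c(0, 1))) rlang::abort("`truth` must be 0/1.")
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("ROC needs at least one positive and one negative example.")
  }
  thr <- sort(unique(probability), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(probability >= t & truth == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(probability >= t & truth == 0) / n_neg, 0)
  pts <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1) {
    pts <- dplyr::bind_rows(pts, tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(roc_points = pts, auc = auc)
}

#' Evaluate clip predictions against reference labels
#'
#' Produces the full evaluation report for a labeled clip set: confusion
#' matrix, precision/recall/F1, ROC points and AUC.
#'
#' @param predictions A tibble with columns `label` (reference 0/1),
#'   `predicted` (0/1), and `probability` (optional; without it the ROC and
#'   AUC are omitted).
#' @return An `eval_report` object; see [tidy.eval_report()],
#'   [glance.eval_report()] and [autoplot.eval_report()].
#' @export
eval_report <- function(predictions) {
  cm <- confusion_counts(predictions$label, predictions$predicted)
  prf <- precision_recall_f1(cm)
  roc <- NULL
  if (!is.null(predictions$probability) &&
      length(unique(predictions$label)) == 2) {
    roc <- roc_auc(predictions$label, predictions$probability)
  }
  structure(list(confusion = cm, precision = prf$precision,
                 recall = prf$recall, f1 = prf$f1,
                 undefined = prf$undefined,
                 roc_points = roc$roc_points, auc = roc$auc,
                 n = nrow(predictions)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d clips\n", x$n))
  print(x$confusion)
  cat(sprintf("precision %.4f | recall %.4f | f1 %.4f", x$precision, x$recall, x$f1))
  if (!is.null(x$auc)) cat(sprintf(" | auc %.4f", x$auc))
  cat("\n")
  invisible(x)
}

#' @rdname eval_report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(metric = c("tp", "fp", "fn", "tn", "precision", "recall", "f1",
                            if (!is.null(x$auc)) "auc"),
                 value = c(x$confusion$tp, x$confusion$fp, x$confusion$fn,
                           x$confusion$tn, x$precision, x$recall, x$f1,
                           if (!is.null(x$auc)) x$auc))
}

#' @rdname eval_report
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n = x$n, precision = x$precision, recall = x$recall,
                 f1 = x$f1, auc = x$auc %||% NA_real_)
}

#' Plot the ROC curve of an evaluation report
#'
#' @param object An [eval_report()] with ROC points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$roc_points)) {
    rlang::abort("this report has no ROC points (probabilities were not supplied).")
  }
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}
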