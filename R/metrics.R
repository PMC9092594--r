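# Confusion counts and the threshold / ranking metric suite.

#' Confusion counts at a decision threshold
#'
#' Prediction is positive iff `score >= threshold`.
#'
#' @param scores Vector of probabilities of the positive class.
#' @param labels Binary labels (0/1), same length.
#' @param threshold Decision threshold, default 0.5.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion(c(0.9, 0.1), c(1, 0))
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) stop("confusion: empty input")
  if (length(scores) != length(labels)) stop("confusion: length mismatch")
  if (!all(labels %in% c(0, 1))) stop("confusion: labels must be 0/1")
  pred <- as.integer(scores >= threshold)
  structure(list(tp = sum(pred == 1L & labels == 1),
                 fp = sum(pred == 1L & labels == 0),
                 tn = sum(pred == 0L & labels == 0),
                 fn = sum(pred == 0L & labels == 1)),
            class = "confusion_counts")
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reported as 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Threshold metrics from confusion counts
#'
#' Sensitivity (= recall = TPR), specificity, precision, accuracy, MCC, F1,
#' FPR and the correct index `(TPR + 1 - FPR) / 2`. All as proportions in
#' \[0, 1\] (MCC in \[-1, 1\]). Metrics with a zero denominator are reported
#' as 0 with a warning. FPR is FP / (FP + TN), the complement of
#' specificity.
#'
#' @param c A `confusion_counts` (or list with `tp`, `fp`, `tn`, `fn`).
#' @return A `metric_report` named list.
#' @export
#' @examples
#' compute_metrics(confusion(c(.9, .8, .2, .4), c(1, 1, 0, 0)))
compute_metrics <- function(c) {
  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)
  tn <- as.numeric(c$tn); fn <- as.numeric(c$fn)
  total <- tp + fp + tn + fn
  if (total == 0) stop("compute_metrics: no evaluated samples")
  se <- safe_div(tp, tp + fn, "sensitivity")
  sp <- safe_div(tn, tn + fp, "specificity")
  prec <- safe_div(tp, tp + fp, "precision")
  acc <- (tp + tn) / total
  mcc_den <- sqrt((tp + fn) * (tp + fp) * (tn + fn) * (tn + fp))
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator); reported as 0", call. = FALSE)
    0
  } else (tp * tn - fp * fn) / mcc_den
  f1 <- if (prec + se == 0) {
    warning("F1 undefined (zero denominator); reported as 0", call. = FALSE)
    0
  } else 2 * prec * se / (prec + se)
  fpr <- safe_div(fp, fp + tn, "FPR")
  structure(list(sensitivity = se, specificity = sp, precision = prec,
                 accuracy = acc, mcc = mcc, f1 = f1,
                 tpr = se, fpr = fpr,
                 correct_index = (se + 1 - fpr) / 2),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  v <- unlist(x)
  cat("<metric_report>\n")
  print(round(v, 4))
  invisible(x)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney probability that a random positive outscores a random
#' negative, ties counted one half, computed from rank sums.
#'
#' @param scores Probabilities (or any monotone scores) of the positive class.
#' @param labels Binary labels (0/1).
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) stop("auc_roc: labels must be 0/1")
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0L || nn == 0L) {
    stop("auc_roc: undefined, need at least one positive and one negative label")
  }
  r <- rank(scores)  # average ranks give the tie = 1/2 convention
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

# Precision/recall pairs at every distinct score threshold, highest first.
pr_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  ctp <- cumsum(y == 1)
  cfp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tied group
  tp <- ctp[last]; fp <- cfp[last]
  np <- sum(labels == 1)
  data.frame(threshold = s[last], recall = tp / np,
             precision = tp / (tp + fp))
}

#' Area under the precision-recall curve
#'
#' Step interpolation (average precision): the sum over thresholds of the
#' recall increment times the precision at that threshold.
#'
#' @inheritParams auc_roc
#' @return AUC-PR in \[0, 1\].
#' @export
auc_pr <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) stop("auc_pr: labels must be 0/1")
  if (sum(labels == 1) == 0L || sum(labels == 0) == 0L) {
    stop("auc_pr: undefined, need both classes")
  }
  pts <- pr_points(scores, labels)
  drec <- diff(c(0, pts$recall))
  sum(drec * pts$precision)
}

# ROC curve points (FPR, TPR) from the highest threshold down, with the
# (0,0) and (1,1) endpoints.
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  ctp <- cumsum(y == 1)
  cfp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, cfp[last] / nn),
             tpr = c(0, ctp[last] / np))
}

#' Full evaluation of scores against labels
#'
#' Threshold metrics at `threshold` plus ROC and PR areas.
#'
#' @inheritParams confusion
#' @return A `metric_report` with `auc_roc` and `auc_pr` fields appended.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  rep <- compute_metrics(confusion(scores, labels, threshold))
  rep$auc_roc <- auc_roc(scores, labels)
  rep$auc_pr <- auc_pr(scores, labels)
  rep
}
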