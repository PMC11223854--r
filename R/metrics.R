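#' Confusion-matrix counts
#'
#' Tallies true/false positives/negatives for binary predictions against
#' ground truth, with amyloid-prone (APR) as the positive class.
#'
#' @param pred,truth Equal-length binary (0/1 or logical) vectors.
#' @return A `confusion_counts` object (named list `TP`, `FP`, `FN`, `TN`).
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop_input("pred (%d) and truth (%d) differ in length",
               length(pred), length(truth))
  }
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (anyNA(pred) || anyNA(truth)) stop_input("pred/truth must be binary with no NA")
  structure(list(TP = sum(pred & truth), FP = sum(pred & !truth),
                 FN = sum(!pred & truth), TN = sum(!pred & !truth)),
            class = "confusion_counts")
}

#' Precision, recall, specificity
#'
#' Prec = TP/(TP+FP), Rec = TP/(TP+FN), Spec = TN/(FP+TN).  A metric whose
#' denominator is zero is undefined and returned as `NA` with a warning, so
#' it can be excluded from averages rather than silently mapped to 0 or 1.
#'
#' @param counts A [confusion_counts][confusion] object, or anything
#'   coercible (named list/vector with TP, FP, FN, TN).
#' @return A one-row tibble with columns `precision`, `recall`,
#'   `specificity`.
#' @export
precision_recall_specificity <- function(counts) {
  counts <- as.list(counts)
  stopifnot(all(c("TP", "FP", "FN", "TN") %in% names(counts)))
  ratio <- function(num, den, name) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator); returning NA", name))
      return(NA_real_)
    }
    num / den
  }
  with(counts, tibble(
    precision = ratio(TP, TP + FP, "precision"),
    recall = ratio(TP, TP + FN, "recall"),
    specificity = ratio(TN, FP + TN, "specificity")))
}

#' ROC and precision-recall curves
#'
#' `roc_curve()` sweeps every distinct score (plus infinite sentinels) as a
#' decision threshold under the rule `score >= threshold` = positive, and
#' returns recall (TPR) against 1 - specificity (FPR) with the area under
#' the curve computed by the trapezoidal rule.  Tied scores share one
#' threshold.  `pr_curve()` returns precision against recall at the same
#' thresholds with the area computed by non-interpolated step summation
#' (average-precision style).
#'
#' @param scores Numeric vector of predicted scores (higher = more positive).
#' @param truth Binary (0/1 or logical) ground-truth vector.
#' @return A tibble of class `roc_curve` (columns `threshold`, `fpr`, `tpr`)
#'   or `pr_curve` (columns `threshold`, `recall`, `precision`), with the
#'   AUC in attribute `"auc"` (also via [glance()]).
#' @examples
#' rc <- roc_curve(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
#' attr(rc, "auc")
#' @export
roc_curve <- function(scores, truth) {
  ok <- check_scores_truth(scores, truth)
  if (length(unique(ok$truth)) < 2) {
    stop_input("ROC needs both classes present in `truth`")
  }
  np <- sum(ok$truth == 1); nn <- sum(ok$truth == 0)
  thr <- c(Inf, sort(unique(ok$scores), decreasing = TRUE), -Inf)
  tp <- fp <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pos <- ok$scores >= thr[i]
    tp[i] <- sum(pos & ok$truth == 1)
    fp[i] <- sum(pos & ok$truth == 0)
  }
  tpr <- tp / np; fpr <- fp / nn
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  out <- tibble(threshold = thr, fpr = fpr, tpr = tpr)
  class(out) <- c("roc_curve", class(out))
  attr(out, "auc") <- auc
  out
}

#' @rdname roc_curve
#' @export
pr_curve <- function(scores, truth) {
  ok <- check_scores_truth(scores, truth)
  np <- sum(ok$truth == 1)
  if (np == 0) stop_input("PR curve needs at least one positive in `truth`")
  thr <- sort(unique(ok$scores), decreasing = TRUE)
  rec <- prec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pos <- ok$scores >= thr[i]
    tp <- sum(pos & ok$truth == 1)
    rec[i] <- tp / np
    prec[i] <- tp / sum(pos)
  }
  # step-wise (non-interpolated) area: sum of precision * recall increments
  auc <- sum(diff(c(0, rec)) * prec)
  out <- tibble(threshold = thr, recall = rec, precision = prec)
  class(out) <- c("pr_curve", class(out))
  attr(out, "auc") <- auc
  out
}

check_scores_truth <- function(scores, truth) {
  if (length(scores) != length(truth)) {
    stop_input("scores (%d) and truth (%d) differ in length",
               length(scores), length(truth))
  }
  truth <- as.numeric(as.logical(truth))
  if (anyNA(scores) || anyNA(truth) || any(!is.finite(scores))) {
    stop_input("scores/truth must be finite with no NA")
  }
  list(scores = as.numeric(scores), truth = truth)
}

# Rank-based AUC (Mann-Whitney with ties counted 1/2); equals the
# trapezoidal ROC AUC and is O(n log n), used inside training loops.
auc_rank <- function(scores, truth) {
  truth <- as.numeric(as.logical(truth))
  np <- sum(truth == 1); nn <- sum(truth == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Youden-J optimal threshold
#'
#' Finds the ROC threshold maximizing J = recall + specificity - 1
#' (equivalently TPR - FPR).  Ties are broken toward the smallest
#' threshold.
#'
#' @param roc A [roc_curve()] result.
#' @return A list with `threshold` and `J`.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$tpr - roc$fpr
  best <- max(j)
  cand <- roc$threshold[j >= best - 1e-15]
  list(threshold = min(cand), J = best)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' @export
glance.roc_curve <- function(x, ...) {
  tibble(auc = attr(x, "auc"), n_thresholds = nrow(x))
}

#' @export
glance.pr_curve <- glance.roc_curve
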