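#' Confusion counts from paired binary labels and predictions
#'
#' @param labels,predictions Equal-length 0/1 vectors (1 = positive).
#' @return A `confusion_counts` list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_from_predictions <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop_dim("confusion_from_predictions", length(labels),
             length(predictions))
  }
  confusion_counts(TP = sum(labels == 1 & predictions == 1),
                   TN = sum(labels == 0 & predictions == 0),
                   FP = sum(labels == 0 & predictions == 1),
                   FN = sum(labels == 1 & predictions == 0))
}

#' @rdname confusion_from_predictions
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, sensitivity, specificity and Matthews correlation
#' coefficient as percentages, plus both error-rate conventions found in
#' the field's reporting: `er_formula = 1 - 0.5 * (SEN + SPC) / 100` (the
#' balanced-error form) and `er_complement = 1 - ACC / 100`.  The two
#' disagree whenever the classes are imbalanced; both are reported so the
#' caller never has to guess which one a table used.
#'
#' When any factor of the MCC denominator is zero the coefficient is
#' reported as 0 with `mcc_degenerate = TRUE`.
#'
#' @param counts A `confusion_counts` object.
#' @return A `metrics_report` list with `acc`, `sen`, `spc`, `mcc`
#'   (percent), `er_formula`, `er_complement` and `mcc_degenerate`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total < 1) stop("empty confusion matrix", call. = FALSE)
  acc <- (TP + TN) / total * 100
  sen <- if (TP + FN > 0) TP / (TP + FN) * 100 else NA_real_
  spc <- if (TN + FP > 0) TN / (TN + FP) * 100 else NA_real_
  denom2 <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  degenerate <- denom2 == 0
  mcc <- if (degenerate) {
    0
  } else {
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom2) * 100
  }
  structure(list(acc = acc, sen = sen, spc = spc, mcc = mcc,
                 er_formula = 1 - 0.5 * (sen + spc) / 100,
                 er_complement = 1 - acc / 100,
                 mcc_degenerate = degenerate,
                 counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("ACC %.*g%%  SEN %.*g%%  SPC %.*g%%  MCC %.*g%%\n",
              digits, x$acc, digits, x$sen, digits, x$spc, digits, x$mcc))
  cat(sprintf("E.R (balanced) %.*g   E.R (1 - ACC) %.*g%s\n",
              digits, x$er_formula, digits, x$er_complement,
              if (x$mcc_degenerate) "   [MCC degenerate]" else ""))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(acc = x$acc, sen = x$sen, spc = x$spc, mcc = x$mcc,
             er_formula = x$er_formula, er_complement = x$er_complement)
}

#' Receiver operating characteristic curve and AUC
#'
#' Sweeps the decision threshold over the distinct scores in descending
#' order (tied scores grouped at one threshold), producing the
#' (false-positive-rate, true-positive-rate) staircase from (0, 0) to
#' (1, 1); the area under the curve is the trapezoid-rule integral.
#'
#' @param scores Numeric decision scores (larger = more positive).
#' @param labels 0/1 vector; both classes must be present.
#' @return A `roc_curve` object: data frame `points` with `fpr`, `tpr`
#'   and `threshold`, plus the scalar `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_dim("roc_curve", length(scores), length(labels))
  }
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC curve undefined: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)   # last index of each tied block
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr,
                                     threshold = c(Inf, s[keep])),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, %d points, AUC %.4f\n",
              x$n_pos, x$n_neg, nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Partitions the index set into `k` folds so that the per-class fold
#' sizes differ by at most one; reproducible under a fixed seed.
#'
#' @param labels Class vector (any type coercible to factor); every class
#'   must have at least `k` members.
#' @param k Number of folds, `>= 2`.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_kfold <- function(labels, k, seed = 1) {
  stopifnot(k >= 2)
  f <- as.factor(labels)
  counts <- table(f)
  if (any(counts < k)) {
    stop(sprintf("class '%s' has fewer than k = %d members",
                 names(counts)[which.min(counts)], k), call. = FALSE)
  }
  fold <- integer(length(f))
  with_seed(seed, {
    for (cl in levels(f)) {
      idx <- which(f == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}
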