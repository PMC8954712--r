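#' Build a confusion table
#'
#' Counts of true positives, true negatives, false positives and false
#' negatives for a binary classifier, with the potent class (`"P"`) as
#' positive.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return object of class `confusion_table`.
#' @export
confusion_table <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  structure(as.list(counts), class = "confusion_table")
}

#' Confusion table from true and predicted labels
#'
#' @param truth true class labels.
#' @param predicted predicted class labels.
#' @param positive label of the positive class (default `"P"`).
#' @return object of class `confusion_table`.
#' @export
confusion_from_labels <- function(truth, predicted, positive = "P") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` lengths differ", call. = FALSE)
  confusion_table(
    tp = sum(truth == positive & predicted == positive),
    tn = sum(truth != positive & predicted != positive),
    fp = sum(truth != positive & predicted == positive),
    fn = sum(truth == positive & predicted != positive)
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("confusion: TP %d TN %d FP %d FN %d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Sensitivity (true positive rate)
#'
#' `SE = TP / (TP + FN)`; `NA` when no positives exist.
#'
#' @param ct a [confusion_table()].
#' @return fraction in \[0, 1\], or `NA` if undefined.
#' @export
sensitivity <- function(ct) {
  if ((ct$tp + ct$fn) == 0) return(NA_real_)
  ct$tp / (ct$tp + ct$fn)
}

#' Specificity (true negative rate)
#'
#' `SP = TN / (TN + FP)`; `NA` when no negatives exist.
#'
#' @inheritParams sensitivity
#' @return fraction in \[0, 1\], or `NA` if undefined.
#' @export
specificity <- function(ct) {
  if ((ct$tn + ct$fp) == 0) return(NA_real_)
  ct$tn / (ct$tn + ct$fp)
}

#' Classification accuracy
#'
#' `CA = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @inheritParams sensitivity
#' @return fraction in \[0, 1\].
#' @export
accuracy <- function(ct) {
  total <- ct$tp + ct$tn + ct$fp + ct$fn
  if (total == 0) stop("empty confusion table", call. = FALSE)
  (ct$tp + ct$tn) / total
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TN+FN)(TN+FP)(TP+FN)(TP+FP))`. When any
#' marginal factor is zero the coefficient is undefined and `NA` is
#' returned (rendered as `"-"` in reports); this happens e.g. for a
#' degenerate classifier that predicts a single class.
#'
#' @inheritParams sensitivity
#' @return value in \[-1, 1\], or `NA` if undefined.
#' @export
mcc <- function(ct) {
  f <- c(ct$tn + ct$fn, ct$tn + ct$fp, ct$tp + ct$fn, ct$tp + ct$fp)
  if (any(f == 0)) return(NA_real_)
  (ct$tp * ct$tn - ct$fp * ct$fn) / sqrt(prod(f))
}

#' Balanced accuracy
#'
#' The mean of sensitivity and specificity, `BA = (SE + SP) / 2`,
#' full-precision. Report rendering (see [render_tables()]) instead
#' averages the 3-decimal rounded SE and SP, the convention under which
#' printed metric rows are self-consistent.
#'
#' @inheritParams sensitivity
#' @return fraction in \[0, 1\], or `NA` if SE or SP is undefined.
#' @export
balanced_accuracy <- function(ct) {
  se <- sensitivity(ct); sp <- specificity(ct)
  if (is.na(se) || is.na(sp)) return(NA_real_)
  (se + sp) / 2
}

#' Area under the ROC curve
#'
#' Computed either as the Mann-Whitney concordance probability (a random
#' positive outscores a random negative, ties counted 1/2) or by
#' trapezoidal integration of the empirical ROC curve; the two are
#' mathematically identical and serve as mutual cross-checks.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels class labels aligned with `scores`.
#' @param positive label of the positive class.
#' @param method `"concordance"` (default) or `"trapezoid"`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive = "P",
                    method = c("concordance", "trapezoid")) {
  method <- match.arg(method)
  if (length(scores) != length(labels))
    stop("`scores` and `labels` lengths differ", call. = FALSE)
  pos <- as.character(labels) == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0)
    stop("AUC needs both classes present", call. = FALSE)
  if (method == "concordance") {
    r <- rank(scores)
    (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  } else {
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; p <- pos[ord]
    # walk distinct thresholds; ties advance TPR and FPR jointly
    last_of_tie <- !duplicated(s, fromLast = TRUE)
    tpr <- c(0, cumsum(p)[last_of_tie] / np)
    fpr <- c(0, cumsum(!p)[last_of_tie] / nn)
    sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  }
}

#' Round half away from zero
#'
#' Decimal rounding in which .5 always rounds up in magnitude (the
#' convention of most published tables), unlike R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Full metric bundle for one confusion table
#'
#' @inheritParams sensitivity
#' @param auc optional AUC (needs the underlying scores; `NA` if absent).
#' @return one-row data frame with columns `AUC`, `CA`, `MCC`, `TP`, `TN`,
#'   `FP`, `FN`, `SE`, `SP`, `BA` (full precision).
#' @export
metrics_bundle <- function(ct, auc = NA_real_) {
  data.frame(AUC = auc, CA = accuracy(ct), MCC = mcc(ct),
             TP = ct$tp, TN = ct$tn, FP = ct$fp, FN = ct$fn,
             SE = sensitivity(ct), SP = specificity(ct),
             BA = balanced_accuracy(ct))
}

#' Display-rounded metric bundle
#'
#' Rounds every metric half-up to 3 decimals and derives BA from the
#' rounded SE and SP, matching how such rows are conventionally printed;
#' undefined values become `NA` (rendered `"-"`).
#'
#' @inheritParams metrics_bundle
#' @return one-row data frame of display values.
#' @export
report_metrics <- function(ct, auc = NA_real_) {
  b <- metrics_bundle(ct, auc)
  for (col in c("AUC", "CA", "MCC", "SE", "SP"))
    b[[col]] <- round_half_up(b[[col]], 3)
  b$BA <- if (is.na(b$SE) || is.na(b$SP)) NA_real_ else
    round_half_up((b$SE + b$SP) / 2, 3)
  b
}

fmt_metric <- function(x) ifelse(is.na(x), "-", sprintf("%.3f", x))
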