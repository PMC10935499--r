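# The 10-metric evaluation suite: ROC-AUC (rank / pairwise definition, ties
# counted 1/2), AUC-PR (step-wise average-precision summation, not
# trapezoidal), and thresholded metrics (balanced accuracy, precision,
# recall, F0.5/F1/F2, Matthews correlation) at score >= threshold, plus
# log loss with probability clipping at 1e-15.

#' Area under the ROC curve (rank definition, ties counted 1/2)
#' @param labels Binary 0/1 labels (both classes present).
#' @param scores Numeric scores.
#' @return ROC-AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  pos <- labels == 1
  P <- sum(pos); N <- sum(!pos)
  r <- rank(scores)  # midranks handle ties
  (sum(r[pos]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve (step-wise summation)
#'
#' Average-precision convention: AP = sum over descending distinct score
#' thresholds of (recall increment) x (precision at that threshold).
#' @inheritParams roc_auc
#' @return AUC-PR in \[0, 1\].
#' @export
auc_pr <- function(labels, scores) {
  P <- sum(labels == 1)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y == 1)
  n_pred <- seq_along(y)
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)  # threshold boundaries
  tp <- tp[last_of_tie]
  n_pred <- n_pred[last_of_tie]
  prec <- tp / n_pred
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Compute the full 10-metric report
#'
#' @param labels Binary 0/1 labels with both classes present.
#' @param scores Case-probabilities in \[0, 1\] (no NaN).
#' @param threshold Decision threshold for the confusion-matrix metrics
#'   (prediction = 1 iff score >= threshold).
#' @return A `metrics_report`: named list with `roc_auc`, `auc_pr`,
#'   `balanced_accuracy`, `precision`, `recall`, `f_half`, `f1`, `f2`,
#'   `log_loss`, `mcc` and the `threshold` used. Undefined ratios
#'   (zero-denominator precision, F-scores, MCC) are reported as 0.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.numeric(labels)
  scores <- as.numeric(scores)
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length", call. = FALSE)
  if (anyNA(scores) || any(is.nan(scores)))
    stop("NaN/NA scores are not allowed", call. = FALSE)
  if (any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  if (!all(labels %in% c(0, 1)) || !any(labels == 1) || !any(labels == 0))
    stop("labels must be binary with both classes present", call. = FALSE)

  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)

  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  tnr <- safe_div(tn, tn + fp)
  fbeta <- function(beta) {
    den <- beta^2 * precision + recall
    if (den == 0) 0 else (1 + beta^2) * precision * recall / den
  }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  p_clip <- pmin(pmax(scores, 1e-15), 1 - 1e-15)
  log_loss <- -mean(labels * log(p_clip) + (1 - labels) * log(1 - p_clip))

  structure(list(roc_auc = roc_auc(labels, scores),
                 auc_pr = auc_pr(labels, scores),
                 balanced_accuracy = (recall + tnr) / 2,
                 precision = precision, recall = recall,
                 f_half = fbeta(0.5), f1 = fbeta(1), f2 = fbeta(2),
                 log_loss = log_loss, mcc = mcc,
                 threshold = threshold),
            class = "metrics_report")
}

METRIC_NAMES <- c("roc_auc", "auc_pr", "balanced_accuracy", "precision",
                  "recall", "f_half", "f1", "f2", "log_loss", "mcc")

# One tidy row per metric.
metrics_rows <- function(report) {
  tibble::tibble(metric = METRIC_NAMES,
                 value = unlist(report[METRIC_NAMES], use.names = FALSE))
}

#' @export
print.metrics_report <- function(x, ...) {
  vals <- unlist(x[METRIC_NAMES])
  cat("<metrics_report (threshold ", x$threshold, ")>\n", sep = "")
  print(round(vals, 4))
  invisible(x)
}
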