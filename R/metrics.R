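#' Classification evaluation metrics
#'
#' The six metrics used to judge BP-variation classifiers: accuracy, area
#' under the ROC curve, Matthews correlation coefficient, F1 score, Cohen's
#' kappa, and area under the precision-recall curve.
#'
#' Degenerate denominators are defined explicitly: a single-class
#' *prediction* gives `mcc = 0` and `kappa = 0`, and `f1 = 0` when no true
#' or predicted positives exist. A single-class *truth* leaves ROC-AUC and
#' AUPRC undefined — [roc_auc()] and [pr_auc()] raise an error there, and
#' [evaluate_predictions()] reports them as `NA` with a warning while still
#' computing the other metrics.
#'
#' @param y_true Integer 0/1 vector of true labels.
#' @param y_pred Integer 0/1 vector of predicted labels.
#' @param y_score Numeric scores (larger means more positive) for the
#'   ranking metrics.
#'
#' @return `evaluate_predictions()` returns a one-row tibble with columns
#'   `acc`, `auc`, `mcc`, `f1`, `kappa`, `auprc`.
#' @export
#' @examples
#' evaluate_predictions(c(0, 0, 1, 1), c(0, 1, 1, 1), c(0.1, 0.6, 0.8, 0.9))
evaluate_predictions <- function(y_true, y_pred, y_score = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length.", call. = FALSE)
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  n <- length(y_true)

  acc <- (tp + tn) / n

  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  mcc <- min(1, max(-1, mcc))  # guard float round-off at the extremes

  f1_den <- 2 * tp + fp + fn
  f1 <- if (f1_den == 0) 0 else 2 * tp / f1_den

  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (pe == 1) 0 else (acc - pe) / (1 - pe)

  two_class <- length(unique(y_true)) == 2
  if (!is.null(y_score) && two_class) {
    auc <- roc_auc(y_true, y_score)
    auprc <- pr_auc(y_true, y_score)
  } else {
    if (!two_class) warning("single-class truth: ROC-AUC and AUPRC undefined (NA).")
    auc <- NA_real_
    auprc <- NA_real_
  }
  tibble::tibble(acc = acc, auc = auc, mcc = mcc, f1 = f1,
                 kappa = kappa, auprc = auprc)
}

#' @rdname evaluate_predictions
#' @details `roc_auc()` is the trapezoidal area under the ROC curve swept
#'   over all score thresholds, computed via the rank (Mann-Whitney)
#'   identity, which handles tied scores by trapezoidal interpolation.
#' @export
roc_auc <- function(y_true, y_score) {
  np <- sum(y_true == 1); nn <- sum(y_true == 0)
  if (np == 0 || nn == 0) stop("ROC-AUC undefined for single-class truth.", call. = FALSE)
  r <- rank(y_score, ties.method = "average")
  (sum(r[y_true == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' @rdname evaluate_predictions
#' @details `pr_auc()` is the step integral of the precision-recall curve
#'   (average precision): the sum over score thresholds of the recall
#'   increment times the precision at that threshold.
#' @export
pr_auc <- function(y_true, y_score) {
  np <- sum(y_true == 1)
  if (np == 0 || all(y_true == 1)) {
    stop("AUPRC undefined for single-class truth.", call. = FALSE)
  }
  ord <- order(y_score, decreasing = TRUE)
  y <- y_true[ord]
  s <- y_score[ord]
  tp <- cumsum(y == 1)
  pp <- seq_along(y)
  # evaluate at the last index of each tied-score block
  last_of_block <- c(s[-length(s)] != s[-1], TRUE)
  tp_b <- tp[last_of_block]
  pp_b <- pp[last_of_block]
  recall <- tp_b / np
  precision <- tp_b / pp_b
  sum(diff(c(0, recall)) * precision)
}
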