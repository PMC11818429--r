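# Multi-label evaluation in the Chou set-overlap style, plus per-label
# binary metrics. Conventions for degenerate sets: a ratio whose
# denominator set is empty contributes 0, except when both the true and
# predicted sets are empty, in which case the sample is a perfect match
# and contributes 1.

as_bitmat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  x
}

#' Multi-label set-overlap metrics
#'
#' For true set Y and predicted set Y* per sample:
#' precision (aiming) = |Y n Y*| / |Y*|, coverage = |Y n Y*| / |Y|,
#' accuracy = |Y n Y*| / |Y u Y*|, absolute true = 1 iff Y = Y*, and
#' absolute false = (|Y u Y*| - |Y n Y*|) / M; all averaged over samples.
#'
#' @param truth n x M 0/1 matrix of true label sets.
#' @param pred n x M 0/1 matrix of predicted label sets.
#' @return A `multilabel_report` list: precision, coverage, accuracy,
#'   absolute_true, absolute_false, n_samples.
#' @export
multilabel_metrics <- function(truth, pred) {
  truth <- as_bitmat(truth)
  pred <- as_bitmat(pred)
  if (!all(dim(truth) == dim(pred))) {
    stop("truth is ", nrow(truth), "x", ncol(truth), " but pred is ",
         nrow(pred), "x", ncol(pred))
  }
  n <- nrow(truth)
  M <- ncol(truth)
  inter <- rowSums(truth & pred)
  uni <- rowSums(truth | pred)
  nt <- rowSums(truth)
  np <- rowSums(pred)
  both_empty <- uni == 0L
  ratio <- function(num, den) ifelse(both_empty, 1, ifelse(den == 0L, 0,
                                                           num / den))
  structure(list(
    precision = mean(ratio(inter, np)),
    coverage = mean(ratio(inter, nt)),
    accuracy = mean(ratio(inter, uni)),
    absolute_true = mean(rowSums(truth == pred) == M),
    absolute_false = mean((uni - inter) / M),
    n_samples = n), class = "multilabel_report")
}

#' @export
print.multilabel_report <- function(x, ...) {
  cat(sprintf(paste0("multi-label metrics over %d samples:\n",
                     "  precision (aiming) %.4f\n  coverage           %.4f\n",
                     "  accuracy           %.4f\n  absolute true      %.4f\n",
                     "  absolute false     %.4f\n"),
              x$n_samples, x$precision, x$coverage, x$accuracy,
              x$absolute_true, x$absolute_false))
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney with mid-ranks for ties)
#'
#' @param truth 0/1 vector.
#' @param scores Numeric scores.
#' @return AUC in \[0, 1\], or NA (with a warning) when only one class is
#'   present.
#' @export
rank_auc <- function(truth, scores) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics for one label
#'
#' Decisions use strict `score > threshold`. MCC uses the standard
#' determinant formula with the 0/0 convention: a zero denominator factor
#' yields MCC = 0.
#'
#' @param truth 0/1 vector.
#' @param scores Probability scores.
#' @param threshold Decision threshold (default 0.5).
#' @return A `binary_report` list: sensitivity, specificity, accuracy,
#'   mcc, auc and the confusion counts.
#' @export
binary_metrics <- function(truth, scores, threshold = 0.5) {
  truth <- as.integer(truth)
  pred <- as.integer(scores > threshold)
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == 0L & pred == 1L)
  tn <- sum(truth == 0L & pred == 0L)
  fn <- sum(truth == 1L & pred == 0L)
  sen <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(truth)
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  auc <- rank_auc(truth, scores)
  structure(list(sensitivity = sen, specificity = spe, accuracy = acc,
                 mcc = mcc, auc = auc,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn)),
            class = "binary_report")
}

#' @export
print.binary_report <- function(x, ...) {
  cat(sprintf("binary metrics: SEN %.4f SPE %.4f ACC %.4f MCC %.4f AUC %s\n",
              x$sensitivity, x$specificity, x$accuracy, x$mcc,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  print(x$confusion)
  invisible(x)
}

#' Per-label 2x2 confusion matrices
#'
#' @param truth n x M 0/1 matrix.
#' @param pred n x M 0/1 matrix.
#' @param labels Label names for the result list.
#' @return Named list of M 2x2 matrices (rows = truth 1/0, columns =
#'   predicted 1/0), each summing to n.
#' @export
per_label_confusions <- function(truth, pred, labels = label_space()) {
  truth <- as_bitmat(truth)
  pred <- as_bitmat(pred)
  stopifnot(all(dim(truth) == dim(pred)), ncol(truth) == length(labels))
  out <- lapply(seq_along(labels), function(j) {
    m <- matrix(c(sum(truth[, j] == 1L & pred[, j] == 1L),
                  sum(truth[, j] == 1L & pred[, j] == 0L),
                  sum(truth[, j] == 0L & pred[, j] == 1L),
                  sum(truth[, j] == 0L & pred[, j] == 0L)),
                2L, 2L, byrow = TRUE,
                dimnames = list(truth = c("1", "0"), pred = c("1", "0")))
    m
  })
  names(out) <- labels
  out
}

#' Full evaluation report: multi-label plus per-label binary metrics
#'
#' @param truth n x M 0/1 matrix of true labels.
#' @param probs n x M probability matrix.
#' @param threshold Decision threshold.
#' @param labels Label names.
#' @return List with `multilabel` ([multilabel_metrics()]), `per_label`
#'   (one [binary_metrics()] per label) and `confusions`.
#' @export
evaluate_predictions <- function(truth, probs, threshold = 0.5,
                                 labels = label_space()) {
  truth <- as_bitmat(truth)
  pred <- decide(probs, threshold)
  per_label <- lapply(seq_along(labels), function(j) {
    binary_metrics(truth[, j], probs[, j], threshold)
  })
  names(per_label) <- labels
  list(multilabel = multilabel_metrics(truth, pred),
       per_label = per_label,
       confusions = per_label_confusions(truth, pred, labels))
}
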