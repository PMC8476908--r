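# Evaluation: accuracy, one-vs-rest precision/recall/F1, ROC/AUC and
# confusion matrices.

as_predictions <- function(result) {
  if (inherits(result, "epid_experiment")) result <- result$predictions
  stopifnot(is.data.frame(result), all(c("truth", "pred") %in% names(result)))
  result
}

#' Classification accuracy
#'
#' Fraction of samples classified correctly,
#' `(TP + TN) / (TP + TN + FP + FN)` in the binary case.
#'
#' @param result an `epid_experiment` or a tibble with `truth` and `pred`
#'   columns.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(result) {
  r <- as_predictions(result)
  if (nrow(r) == 0) stop("no samples to evaluate", call. = FALSE)
  mean(r$truth == r$pred)
}

#' Confusion matrix
#'
#' Counts of (true, predicted) label pairs over a fixed class set.
#'
#' @param result an `epid_experiment` or prediction tibble.
#' @param classes class labels ordering the rows/columns; defaults to the
#'   sorted union of observed labels.
#' @return A `confusion_matrix`: an n x n integer matrix, true classes in
#'   rows, predictions in columns.
#' @export
confusion <- function(result, classes = NULL) {
  r <- as_predictions(result)
  if (nrow(r) == 0) stop("no samples to evaluate", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(r$truth, r$pred)))
  cm <- table(factor(r$truth, levels = classes),
              factor(r$pred, levels = classes))
  structure(unclass(cm), dimnames = list(true = as.character(classes),
                                         predicted = as.character(classes)),
            class = c("confusion_matrix", "matrix", "array"))
}

#' One-vs-rest precision, recall and F1
#'
#' `Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)`,
#' `F1 = 2 * Precision * Recall / (Precision + Recall)`; any zero
#' denominator yields 0.
#'
#' @param cm a [confusion()] matrix (or something coercible via
#'   [confusion()]).
#' @param class the positive class; if `NULL`, all classes are reported.
#' @return A tibble with columns `class`, `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(cm, class = NULL) {
  if (!inherits(cm, "confusion_matrix")) cm <- confusion(cm)
  classes <- rownames(cm)
  if (!is.null(class)) {
    class <- as.character(class)
    stopifnot(class %in% classes)
    classes <- class
  }
  safe_div <- function(num, den) if (den > 0) num / den else 0
  rows <- lapply(classes, function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[, k]) - tp
    fn <- sum(cm[k, ]) - tp
    tn <- sum(cm) - tp - fp - fn
    precision <- safe_div(tp, tp + fp)
    recall <- safe_div(tp, tp + fn)
    f1 <- safe_div(2 * precision * recall, precision + recall)
    tibble::tibble(class = k, tp = tp, fp = fp, fn = fn, tn = tn,
                   precision = precision, recall = recall, f1 = f1)
  })
  dplyr::bind_rows(rows)
}

#' ROC curve and AUC for a binary task
#'
#' Sweeps all score thresholds, collecting (FPR, TPR) points, and integrates
#' the curve with the trapezoidal rule; with ties handled by threshold
#' grouping this equals the Mann-Whitney concordance probability.
#'
#' @param result an `epid_experiment` or prediction tibble; scores for the
#'   positive class are taken from `score` or `score_<positive>` columns.
#' @param positive the positive class label (default 2, "error present").
#' @return A list with `curve` (tibble of `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(result, positive = 2) {
  r <- as_predictions(result)
  score_col <- if ("score" %in% names(r)) "score"
               else paste0("score_", positive)
  if (!score_col %in% names(r))
    stop("no score column for the positive class", call. = FALSE)
  truth <- r$truth == positive
  if (all(truth) || !any(truth))
    stop("ROC needs both classes present in the truth", call. = FALSE)
  s <- r[[score_col]]
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; truth <- truth[ord]
  # one point per distinct threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(truth); fp <- cumsum(!truth)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(truth))
  fpr <- c(0, fp[last] / sum(!truth))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(curve = tibble::tibble(threshold = c(Inf, s[last]),
                                        fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "epid_roc")
}

#' Evaluate an experiment
#'
#' Bundles accuracy, the confusion matrix, per-class metrics and (for
#' binary tasks) the ROC curve and AUC.
#'
#' @param result an `epid_experiment` or prediction tibble.
#' @param positive positive class for the ROC (default 2).
#' @return A list with `accuracy`, `confusion`, `per_class` and, when the
#'   task is binary, `roc` and `auc`.
#' @export
evaluate_predictions <- function(result, positive = 2) {
  r <- as_predictions(result)
  cm <- confusion(r)
  out <- list(accuracy = accuracy(r), confusion = cm,
              per_class = precision_recall_f1(cm))
  if (nrow(cm) == 2 && paste0("score_", positive) %in% names(r) ||
      "score" %in% names(r) && nrow(cm) == 2) {
    roc <- roc_auc(r, positive)
    out$roc <- roc$curve
    out$auc <- roc$auc
  }
  out
}
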