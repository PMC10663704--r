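# Evaluation metrics: PSNR/MSE for image restoration, confusion-matrix
# classification metrics, Dice overlap for masks, ROC/AUC by threshold
# sweep, and stratified train/test + k-fold assignments.

#' Mean squared error and peak signal-to-noise ratio
#'
#' `psnr = 10 log10(255^2 / mse)` in dB (8-bit peak); identical images
#' give `mse = 0` and `psnr = Inf`.
#'
#' @param x,ref numeric matrices of the same shape.
#' @return scalar.
#' @export
mse_metric <- function(x, ref) {
  if (!all(dim(x) == dim(ref))) stop("shape mismatch")
  mean((as.numeric(x) - as.numeric(ref))^2)
}

#' @rdname mse_metric
#' @export
psnr_metric <- function(x, ref) {
  m <- mse_metric(x, ref)
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

#' Confusion matrix
#'
#' Rows are truth, columns predictions, in the order of `labels`.
#'
#' @param truth,predicted label vectors.
#' @param labels ordered class names; defaults to the union of observed
#'   labels.
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted,
                             labels = sort(unique(c(truth, predicted)))) {
  truth <- factor(truth, levels = labels)
  predicted <- factor(predicted, levels = labels)
  m <- as.matrix(table(truth = truth, predicted = predicted))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Classification metrics from a confusion matrix
#'
#' For a two-class matrix: `accuracy = trace/total`,
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)` and
#' `ppv = TP/(TP+FP)` with the `positive` class naming the row/column of
#' TP. Accuracy and positive predictive value are reported under
#' distinct names. Three-way label sets that include `suspicious`
#' predictions are collapsed with [collapse_suspicious()] first.
#'
#' @param cm a [confusion_matrix()].
#' @param positive name of the positive class.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `ppv`.
#' @export
classification_metrics <- function(cm, positive = "malignant") {
  if (sum(cm) == 0) stop("empty confusion matrix")
  acc <- sum(diag(cm)) / sum(cm)
  if (!positive %in% rownames(cm))
    return(list(accuracy = acc, sensitivity = NA_real_,
                specificity = NA_real_, ppv = NA_real_))
  tp <- cm[positive, positive]
  fn <- sum(cm[positive, ]) - tp
  fp <- sum(cm[, positive]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(accuracy = acc,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Collapse suspicious predictions for binary bookkeeping
#'
#' The three-way decision is collapsed so that `suspicious` counts on
#' the positive (mass-present) side: a conservative reading in which an
#' unclear case is not reported as clean.
#'
#' @param predicted character vector of predicted labels.
#' @param positive label that suspicious predictions collapse into.
#' @return character vector.
#' @export
collapse_suspicious <- function(predicted, positive = "malignant") {
  predicted[predicted == "suspicious"] <- positive
  predicted
}

#' Dice similarity of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks are identical, so
#' the score is 1 by convention.
#'
#' @param a,b logical matrices on the same frame.
#' @return fraction in `[0, 1]`.
#' @export
dice_coef <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must share a frame")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds (score >= threshold is
#' called positive; tied scores enter together), yielding a monotone
#' (fpr, tpr) curve from (0, 0) to (1, 1); the AUC is its trapezoidal
#' area.
#'
#' @param scores numeric scores, larger = more positive.
#' @param truth logical (or 0/1) vector of positive ground truth.
#' @return list with `points` (data.frame fpr, tpr, threshold) and
#'   `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth))
    stop("need at least one positive and one negative")
  np <- sum(truth); nn <- sum(!truth)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & truth) / np, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !truth) / nn, numeric(1))
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, th))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Stratified 70/30 split and k-fold assignment
#'
#' Cases are shuffled within each class; folds are dealt round-robin so
#' fold sizes differ by at most one and class ratios are preserved
#' within one case. The train/test split takes the first
#' `train_frac` share of each class. A class smaller than `k` triggers
#' a warning and unstratified fold assignment.
#'
#' @param labels class label per case.
#' @param train_frac training fraction in `(0, 1)`.
#' @param k number of folds, >= 2.
#' @param seed RNG seed.
#' @return data.frame with columns `case`, `label`, `fold`, `split`
#'   (`"train"`/`"test"`).
#' @export
split_and_cv <- function(labels, train_frac = 0.7, k = 5, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  n <- length(labels)
  fold <- integer(n); split <- character(n)
  with_local_seed(seed, {
    if (any(table(labels) < k)) {
      warning("a class has fewer cases than k; folds are unstratified")
      perm <- sample(n)
      fold[perm] <- rep(seq_len(k), length.out = n)
      split[perm] <- ifelse(seq_len(n) <= round(train_frac * n),
                            "train", "test")
    } else {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep(seq_len(k), length.out = length(idx))
        ntr <- round(train_frac * length(idx))
        split[idx] <- c(rep("train", ntr),
                        rep("test", length(idx) - ntr))
      }
    }
  })
  data.frame(case = seq_len(n), label = labels, fold = fold, split = split,
             stringsAsFactors = FALSE)
}
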