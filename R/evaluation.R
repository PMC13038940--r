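# Binary-classification metric suite: confusion counts, ACC/Sn/Sp/
# Precision/F1/MCC, rank-based ROC AUC, the balanced (Sn+Sp)/2 summary, and
# a stratified cross-validation driver.
#
# Two "AUC" quantities are deliberately kept distinct: `roc_auc()` is the
# area under the ROC curve (rank statistic, used in all reports) and
# `balanced_auc()` is the closed-form (Sn + Sp) / 2 of a single confusion
# matrix. They are never conflated.

#' Cross-tabulate labels against thresholded probabilities
#'
#' A prediction is positive when its probability is greater than or equal
#' to the threshold (ties count as positive).
#'
#' @param labels Binary labels (PVP = 1).
#' @param probabilities Positive-class probabilities, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return Object of class `confusion_counts`: named integer vector with
#'   elements `TP`, `FN`, `TN`, `FP`.
#' @export
confusion <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) != length(probabilities)) {
    stop("labels and probabilities must have equal length")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  pred <- as.integer(probabilities >= threshold)
  out <- c(TP = sum(labels == 1L & pred == 1L),
           FN = sum(labels == 1L & pred == 0L),
           TN = sum(labels == 0L & pred == 0L),
           FP = sum(labels == 0L & pred == 1L))
  structure(out, class = "confusion_counts")
}

#' Build confusion counts directly
#'
#' @param TP,FN,TN,FP Non-negative integer counts, not all zero.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FN, TN, FP) {
  out <- c(TP = as.integer(TP), FN = as.integer(FN),
           TN = as.integer(TN), FP = as.integer(FP))
  if (any(out < 0L)) stop("confusion counts must be non-negative")
  if (sum(out) == 0L) stop("confusion counts must sum to a positive n")
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts: TP", x["TP"], " FN", x["FN"],
      " TN", x["TN"], " FP", x["FP"], "\n")
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Computes
#' `ACC = (TP+TN)/n`, `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `Precision = TP/(TP+FP)`, `F1 = 2TP/(2TP+FP+FN)` and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA` with a warning
#' (an explicit undefined sentinel), never silently as 0.
#'
#' @param cc A `confusion_counts` object (or named vector with TP/FN/TN/FP).
#' @return Named numeric vector `ACC`, `Sn`, `Sp`, `Precision`, `F1`,
#'   `MCC`.
#' @export
classification_metrics <- function(cc) {
  tp <- as.numeric(cc[["TP"]]); fn <- as.numeric(cc[["FN"]])
  tn <- as.numeric(cc[["TN"]]); fp <- as.numeric(cc[["FP"]])
  n <- tp + fn + tn + fp
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NA",
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  mcc_den <- sqrt((tp + fn) * (tp + fp) * (tn + fp) * (tn + fn))
  c(ACC = safe(tp + tn, n, "ACC"),
    Sn = safe(tp, tp + fn, "Sn"),
    Sp = safe(tn, tn + fp, "Sp"),
    Precision = safe(tp, tp + fp, "Precision"),
    F1 = safe(2 * tp, 2 * tp + fp + fn, "F1"),
    MCC = safe(tp * tn - fp * fn, mcc_den, "MCC"))
}

#' Balanced accuracy of a confusion matrix
#'
#' The closed form `(Sn + Sp) / 2` — the arithmetic mean of sensitivity and
#' specificity of a single thresholded confusion matrix. Distinct from
#' [roc_auc()], which integrates the ROC curve over all thresholds.
#'
#' @inheritParams classification_metrics
#' @return Numeric scalar in `[0, 1]` (NA if Sn or Sp is undefined).
#' @export
balanced_auc <- function(cc) {
  m <- classification_metrics(cc)
  unname((m["Sn"] + m["Sp"]) / 2)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with average ranks for ties:
#' the probability that a random positive scores above a random negative,
#' counting ties as 1/2.
#'
#' @param labels Binary labels with both classes present.
#' @param scores Numeric scores (higher = more PVP-like).
#' @return Numeric AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("ROC AUC requires both classes present")
  r <- rank(scores)                      # average ranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps the sorted unique scores as thresholds (prediction positive when
#' score >= threshold) and returns the operating points, bracketed by the
#' all-positive and all-negative corners.
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1).
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("ROC curve requires both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, 0)
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Stratified k-fold cross-validation of a model builder
#'
#' @param fm A [feature_matrix()] with both classes and `n >= folds`.
#' @param builder Function `(X_train, y_train)` returning an object whose
#'   `stats::predict(object, X)` (or `object$prob(X)` if present) yields
#'   positive-class probabilities.
#' @param folds Number of stratified folds (default 10).
#' @param seed Integer seed for the fold plan.
#' @param threshold Decision threshold (default 0.5).
#' @return List of class `pvp_cv`: `per_fold` (data frame of per-fold
#'   metrics), `pooled` (metric vector over pooled out-of-fold
#'   predictions), `pooled_auc`, `oof` (out-of-fold probability per row),
#'   `fold` (assignment), `seed`.
#' @export
cross_validate <- function(fm, builder, folds = 10L, seed = 1L,
                           threshold = 0.5) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(unique(fm$y)) < 2L) stop("cross-validation requires both classes")
  fold <- stratified_folds(fm$y, folds, seed)
  oof <- rep(NA_real_, nrow(fm$X))
  rows <- list()
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- builder(fm$X[tr, , drop = FALSE], fm$y[tr])
    p <- if (is.list(model) && is.function(model$prob)) {
      model$prob(fm$X[!tr, , drop = FALSE])
    } else {
      stats::predict(model, fm$X[!tr, , drop = FALSE])
    }
    oof[!tr] <- as.numeric(p)
    m <- suppressWarnings(classification_metrics(
      confusion(fm$y[!tr], oof[!tr], threshold)))
    auc_f <- if (length(unique(fm$y[!tr])) == 2L) {
      roc_auc(fm$y[!tr], oof[!tr])
    } else NA_real_
    rows[[f]] <- data.frame(fold = f, t(m), roc_auc = auc_f)
  }
  pooled_cc <- confusion(fm$y, oof, threshold)
  structure(list(per_fold = do.call(rbind, rows),
                 pooled = suppressWarnings(classification_metrics(pooled_cc)),
                 pooled_auc = roc_auc(fm$y, oof),
                 oof = oof, fold = fold, seed = seed),
            class = "pvp_cv")
}

#' @export
print.pvp_cv <- function(x, ...) {
  cat("Stratified ", max(x$fold), "-fold cross-validation\n", sep = "")
  m <- x$pooled
  cat(sprintf("  pooled ACC %.4f  Sn %.4f  Sp %.4f  MCC %.4f  AUC %.4f\n",
              m["ACC"], m["Sn"], m["Sp"], m["MCC"], x$pooled_auc))
  invisible(x)
}

#' Write a metric report as tab-separated text
#'
#' @param metrics_df Data frame of metrics (e.g. `run_grid()$stacked`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(metrics_df, path) {
  utils::write.table(metrics_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
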