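# Feature selection: ANOVA F-score filter, variance filter, and recursive
# feature elimination with cross-validation (RFECV). Selections are fit on
# training data only and replayed on new data by name.

#' Per-feature ANOVA F statistic for a binary target
#'
#' One-way two-group ANOVA F value for every feature:
#' `F_j = [sum_c n_c (xbar_cj - xbar_j)^2 / (C-1)] /
#'        [sum_c sum_{i in c} (x_ij - xbar_cj)^2 / (n-C)]` with C = 2.
#' Features with zero within-class variance but unequal class means score
#' `+Inf` (perfect separation sentinel, ranked first); features constant
#' everywhere score 0.
#'
#' @param fm A [feature_matrix()] containing both classes.
#' @return Named numeric vector of F statistics, one per feature.
#' @export
f_score_rank <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$y
  if (length(unique(y)) < 2L) stop("F score requires both classes present")
  X <- fm$X
  n <- nrow(X)
  n1 <- sum(y == 1L); n0 <- n - n1
  m1 <- colMeans(X[y == 1L, , drop = FALSE])
  m0 <- colMeans(X[y == 0L, , drop = FALSE])
  m <- colMeans(X)
  between <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2          # df = 1
  within <- colSums(sweep(X[y == 1L, , drop = FALSE], 2L, m1)^2) +
            colSums(sweep(X[y == 0L, , drop = FALSE], 2L, m0)^2)
  fstat <- between / (within / (n - 2L))     # within = 0, between > 0 -> Inf
  fstat[within == 0 & between == 0] <- 0     # constant feature
  names(fstat) <- colnames(X)
  fstat
}

new_selection <- function(method, kept_names, scores, params) {
  structure(list(method = method, kept_names = kept_names,
                 scores = scores, params = params),
            class = "pvp_selection")
}

#' @export
print.pvp_selection <- function(x, ...) {
  cat("Feature selection [", x$method, "]: ", length(x$kept_names),
      " features kept\n", sep = "")
  invisible(x)
}

#' Select the top-k features by ANOVA F score
#'
#' Kept features are ordered by F descending; ties are broken by original
#' column order (lower index first).
#'
#' @param fm A [feature_matrix()].
#' @param k Number of features to keep (`k <= d`).
#' @return A `pvp_selection` with method `"F"`.
#' @export
f_select <- function(fm, k) {
  scores <- f_score_rank(fm)
  d <- length(scores)
  if (k < 1L || k > d) stop("k must be in 1..", d)
  ord <- order(-scores, seq_len(d))
  kept <- names(scores)[ord[seq_len(k)]]
  new_selection("F", kept, scores, list(k = k))
}

#' Select features by variance threshold
#'
#' Keeps features whose population variance (denominator n) is at least
#' `threshold`, in their original order.
#'
#' @param fm A [feature_matrix()] with at least two samples.
#' @param threshold Non-negative variance threshold. The default keeps the
#'   top three quarters of features: the 25th percentile of the feature
#'   variances.
#' @return A `pvp_selection` with method `"Var"`.
#' @export
variance_select <- function(fm, threshold = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$X
  if (nrow(X) < 2L) stop("variance selection requires n >= 2")
  v <- colMeans(sweep(X, 2L, colMeans(X))^2)   # population variance, two-pass
  if (is.null(threshold)) threshold <- unname(stats::quantile(v, 0.25))
  if (threshold < 0) stop("threshold must be non-negative")
  kept <- colnames(X)[v >= threshold]
  new_selection("Var", kept, v, list(threshold = threshold))
}

#' Recursive feature elimination with cross-validation (RFECV)
#'
#' Repeatedly fits an importance-yielding estimator and removes the `step`
#' least-important features. The retained feature count is the one
#' maximizing mean cross-validated accuracy over stratified folds (ties go
#' to the smallest count); the final subset is obtained by re-running the
#' elimination on the full data and keeping that many top-ranked features.
#'
#' @param fm A [feature_matrix()].
#' @param estimator `"linear"` (linear max-margin classifier; coefficient
#'   magnitudes as importances) or `"rf"` (random-forest Gini importances).
#' @param cv_folds Number of stratified folds (default 10).
#' @param step Features removed per elimination round (default 1).
#' @param seed Integer seed (fold plan and stochastic estimators).
#' @return A `pvp_selection` with method `"RFECV"`; `scores` holds the
#'   elimination rank (1 = eliminated last / most important).
#' @export
rfecv_select <- function(fm, estimator = c("linear", "rf"), cv_folds = 10L,
                         step = 1L, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  estimator <- match.arg(estimator)
  step <- as.integer(step)
  if (step < 1L) stop("step must be a positive integer")
  n <- nrow(fm$X); d <- ncol(fm$X)
  if (n < cv_folds) stop("n must be at least cv_folds")
  if (length(unique(fm$y)) < 2L) stop("RFECV requires both classes present")
  sizes <- rfe_sizes(d, step)

  if (d == 1L) {
    return(new_selection("RFECV", colnames(fm$X),
                         stats::setNames(1L, colnames(fm$X)),
                         list(estimator = estimator, cv_folds = cv_folds,
                              step = step, seed = seed, n_kept = 1L)))
  }

  folds <- stratified_folds(fm$y, cv_folds, seed)
  acc <- matrix(NA_real_, nrow = cv_folds, ncol = length(sizes))
  for (f in seq_len(cv_folds)) {
    tr <- fm_rows(fm, which(folds != f))
    te <- fm_rows(fm, which(folds == f))
    ranking <- rfe_rank(tr$X, tr$y, estimator, step, seed + f)
    for (s in seq_along(sizes)) {
      keep <- names(ranking)[ranking <= sizes[s]]
      set.seed(seed + 1000L + f)
      fit <- rfe_fit(tr$X[, keep, drop = FALSE], tr$y, estimator)
      pred <- rfe_predict(fit, te$X[, keep, drop = FALSE], estimator)
      acc[f, s] <- mean(pred == te$y)
    }
  }
  mean_acc <- colMeans(acc)
  best_size <- sizes[which(mean_acc == max(mean_acc))]
  n_kept <- min(best_size)                      # ties -> smallest count
  ranking <- rfe_rank(fm$X, fm$y, estimator, step, seed)
  kept <- names(sort(ranking))[seq_len(n_kept)]
  kept <- kept[order(match(kept, colnames(fm$X)))]
  new_selection("RFECV", kept, ranking,
                list(estimator = estimator, cv_folds = cv_folds, step = step,
                     seed = seed, n_kept = n_kept,
                     cv_accuracy = stats::setNames(mean_acc, sizes)))
}

# candidate subset sizes d, d-step, ..., down to 1
rfe_sizes <- function(d, step) {
  sizes <- seq(d, 1L, by = -step)
  if (sizes[length(sizes)] != 1L) sizes <- c(sizes, 1L)
  as.integer(sizes)
}

# full elimination ranking: rank 1 = survives longest
rfe_rank <- function(X, y, estimator, step, seed) {
  remaining <- colnames(X)
  rank_out <- stats::setNames(integer(ncol(X)), colnames(X))
  next_rank <- length(remaining)
  while (length(remaining) > 1L) {
    set.seed(seed)
    fit <- rfe_fit(X[, remaining, drop = FALSE], y, estimator)
    imp <- rfe_importance(fit, remaining, estimator)
    n_drop <- min(step, length(remaining) - 1L)
    drop <- names(sort(imp))[seq_len(n_drop)]   # lowest importance out
    for (nm in rev(drop)) {
      rank_out[nm] <- next_rank
      next_rank <- next_rank - 1L
    }
    remaining <- setdiff(remaining, drop)
  }
  rank_out[remaining] <- 1L
  rank_out
}

rfe_fit <- function(X, y, estimator) {
  if (estimator == "linear") {
    e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
               scale = FALSE, cost = 1)
  } else {
    randomForest::randomForest(X, factor(y, levels = c(0, 1)), ntree = 100L)
  }
}

rfe_importance <- function(fit, feature_names, estimator) {
  if (estimator == "linear") {
    w <- t(fit$coefs) %*% fit$SV              # hyperplane weights
    imp <- abs(as.numeric(w))
    names(imp) <- colnames(fit$SV)
    imp[feature_names]
  } else {
    imp <- randomForest::importance(fit)[, "MeanDecreaseGini"]
    imp[feature_names]
  }
}

rfe_predict <- function(fit, X, estimator) {
  as.integer(as.character(stats::predict(fit, X)))
}

#' Apply a fitted selection to a feature matrix
#'
#' Subsets and reorders columns to the selection's kept features; labels and
#' ids are unchanged. Never recomputes any statistic, so applying a
#' train-time selection to held-out data cannot leak.
#'
#' @param fm A [feature_matrix()] whose features include all kept names.
#' @param sel A `pvp_selection`.
#' @return A [feature_matrix()] with columns `sel$kept_names`, in order.
#' @export
apply_selection <- function(fm, sel) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(sel, "pvp_selection"))
  missing <- setdiff(sel$kept_names, colnames(fm$X))
  if (length(missing)) {
    stop("feature(s) missing from matrix: ", paste(missing, collapse = ", "))
  }
  feature_matrix(fm$X[, sel$kept_names, drop = FALSE], fm$y, fm$ids)
}

#' Serialize a selection to delimited text
#'
#' @param sel A `pvp_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  params <- sel$params[setdiff(names(sel$params), "cv_accuracy")]
  header <- c(paste0("#method\t", sel$method),
              paste0("#param\t", names(params), "\t",
                     vapply(params, function(p) paste(format(p), collapse = ","),
                            character(1))))
  writeLines(c(header, sel$kept_names), path)
  invisible(path)
}

#' Read a selection written by [write_selection()]
#'
#' @param path Input path.
#' @return A `pvp_selection` (scores are not preserved).
#' @export
read_selection <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  kept <- lines[!startsWith(lines, "#")]
  method <- sub("^#method\\t", "", meta[startsWith(meta, "#method")])
  params <- list()
  for (pl in meta[startsWith(meta, "#param")]) {
    toks <- strsplit(pl, "\t")[[1]]
    params[[toks[2]]] <- toks[3]
  }
  new_selection(method, kept, NULL, params)
}
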