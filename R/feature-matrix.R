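# Labeled feature-matrix container used by selection, stacking and
# evaluation. PVP = 1, non-PVP = 0 throughout.

#' Construct a labeled feature matrix
#'
#' @param X Numeric `n x d` matrix with unique column names (features).
#' @param y Binary labels in `{0, 1}` (PVP = 1), length n.
#' @param ids Sample identifiers (default: rownames of `X`, else `s1..sn`).
#' @return An object of class `feature_matrix` with elements `X`, `y`,
#'   `ids`.
#' @export
feature_matrix <- function(X, y, ids = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be a numeric matrix")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stop("X must have unique column (feature) names")
  }
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1 (PVP = 1)")
  if (is.null(ids)) ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  ids <- as.character(ids)
  if (length(ids) != nrow(X) || anyDuplicated(ids)) {
    stop("ids must be unique and match nrow(X)")
  }
  rownames(X) <- ids
  structure(list(X = X, y = y, ids = ids), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix: ", nrow(x$X), " samples x ", ncol(x$X), " features (",
      sum(x$y == 1L), " PVP / ", sum(x$y == 0L), " non-PVP)\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$X)

# row subset helper (keeps labels/ids aligned)
fm_rows <- function(fm, idx) {
  feature_matrix(fm$X[idx, , drop = FALSE], fm$y[idx], fm$ids[idx])
}

#' Split a feature matrix into stratified train and test parts
#'
#' @param fm A [feature_matrix()].
#' @param test_fraction Fraction of each class held out (default 0.3).
#' @param seed Integer seed controlling the split.
#' @return List with `train` and `test` feature matrices.
#' @export
split_feature_matrix <- function(fm, test_fraction = 0.3, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  set.seed(seed)
  test_idx <- integer(0)
  for (cls in c(0L, 1L)) {
    rows <- which(fm$y == cls)
    n_test <- max(1L, round(length(rows) * test_fraction))
    test_idx <- c(test_idx, sample(rows, n_test))
  }
  test_idx <- sort(test_idx)
  list(train = fm_rows(fm, setdiff(seq_len(nrow(fm$X)), test_idx)),
       test = fm_rows(fm, test_idx))
}
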