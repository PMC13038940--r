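# Two-layer stacked ensemble: per-selector base layers produce 10-fold
# out-of-fold positive-class probabilities, which concatenate into the
# meta-feature matrix for a logistic-regression / random-forest / SVM
# meta-classifier. The default configuration is the best-performing one of
# the framework: F-score + RFECV meta-feature blocks with an RF meta model.

#' Specify the first (base) layer of the stack
#'
#' @param algorithms Ordered algorithm tags; default is every tag with an
#'   installed backend (see [available_algorithms()]; the full roster is
#'   [all_algorithms()]). Requesting a tag without a backend is an error at
#'   fit time, never a silent skip.
#' @param folds Number of stratified cross-validation folds used to build
#'   out-of-fold meta-features (default 10).
#' @param seed Integer seed governing the shared fold plan and every
#'   stochastic learner.
#' @param params Named list of per-algorithm hyperparameter overrides, e.g.
#'   `list(RF = list(ntree = 500))`.
#' @return An object of class `base_layer_spec`.
#' @export
base_layer_spec <- function(algorithms = available_algorithms(),
                            folds = 10L, seed = 1L, params = list()) {
  algorithms <- as.character(algorithms)
  if (anyDuplicated(algorithms)) stop("algorithm tags must be unique")
  unknown <- setdiff(algorithms, all_algorithms())
  if (length(unknown)) {
    stop("unknown algorithm tag(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(algorithms = algorithms, folds = as.integer(folds),
                 seed = as.integer(seed), params = params),
            class = "base_layer_spec")
}

# deterministic per-(algorithm, fold) seed; fold 0 = full-data refit
learner_seed <- function(spec_seed, algo_index, fold) {
  (spec_seed * 997L + algo_index * 131L + fold) %% .Machine$integer.max
}

#' Fit the base layer and its out-of-fold meta-features
#'
#' For every algorithm, the shared stratified fold plan is traversed: the
#' model trained on all folds but f predicts the positive-class probability
#' of fold f's rows, assembling a full-length out-of-fold (OOF) column. A
#' final model refit on all rows is stored for inference. Each training
#' row's OOF value therefore comes from a model whose training data excluded
#' that row.
#'
#' @param fm A [feature_matrix()] (already reduced by a selector) with both
#'   classes and `n >= folds`.
#' @param spec A [base_layer_spec()].
#' @return An object of class `base_layer_fit`: `oof` (n x m probability
#'   matrix, columns = algorithm tags), `models` (full-data refits),
#'   `folds` (fold id per row), `spec`, `feature_names`, `ids`.
#' @export
fit_base_layer <- function(fm, spec = base_layer_spec()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(spec, "base_layer_spec"))
  unavailable <- setdiff(spec$algorithms, available_algorithms())
  if (length(unavailable)) {
    stop("no installed backend for algorithm(s): ",
         paste(unavailable, collapse = ", "),
         "; drop them from the spec or install a backend")
  }
  n <- nrow(fm$X)
  if (length(unique(fm$y)) < 2L) stop("base layer requires both classes")
  if (n < spec$folds) stop("n (", n, ") must be at least folds (", spec$folds, ")")
  folds <- stratified_folds(fm$y, spec$folds, spec$seed)
  for (f in seq_len(spec$folds)) {
    if (length(unique(fm$y[folds != f])) < 2L) {
      stop("fold ", f, " leaves a single-class training set; use fewer folds")
    }
  }
  oof <- matrix(NA_real_, n, length(spec$algorithms),
                dimnames = list(fm$ids, spec$algorithms))
  models <- vector("list", length(spec$algorithms))
  names(models) <- spec$algorithms
  for (a in seq_along(spec$algorithms)) {
    tag <- spec$algorithms[a]
    backend <- learner_backend(tag)
    pars <- spec$params[[tag]] %||% list()
    for (f in seq_len(spec$folds)) {
      tr <- folds != f
      model_f <- backend$fit(fm$X[tr, , drop = FALSE], fm$y[tr],
                             learner_seed(spec$seed, a, f), pars)
      oof[!tr, a] <- backend$prob(model_f, fm$X[!tr, , drop = FALSE])
    }
    models[[a]] <- backend$fit(fm$X, fm$y, learner_seed(spec$seed, a, 0L), pars)
  }
  stopifnot(!anyNA(oof), all(oof >= 0 & oof <= 1))
  structure(list(oof = oof, models = models, folds = folds, spec = spec,
                 feature_names = colnames(fm$X), ids = fm$ids, y = fm$y),
            class = "base_layer_fit")
}

#' Base-layer probabilities for new samples
#'
#' @param fit A `base_layer_fit`.
#' @param X Numeric matrix containing at least the fit's feature columns.
#' @return n x m matrix of positive-class probabilities from the full-data
#'   refit models.
#' @export
predict_base_layer <- function(fit, X) {
  stopifnot(inherits(fit, "base_layer_fit"))
  missing <- setdiff(fit$feature_names, colnames(X))
  if (length(missing)) {
    stop("feature(s) missing from newdata: ", paste(missing, collapse = ", "))
  }
  X <- X[, fit$feature_names, drop = FALSE]
  out <- matrix(NA_real_, nrow(X), length(fit$spec$algorithms),
                dimnames = list(rownames(X), fit$spec$algorithms))
  for (a in seq_along(fit$spec$algorithms)) {
    backend <- learner_backend(fit$spec$algorithms[a])
    out[, a] <- backend$prob(fit$models[[a]], X)
  }
  out
}

#' Concatenate per-selector meta-feature blocks
#'
#' Blocks are column-bound in the fixed selector order F, Var, RFECV;
#' column names are `<selector>.<algorithm>`. All blocks must carry the
#' same samples in the same order.
#'
#' @param blocks Named list (names among `F`, `Var`, `RFECV`) of matrices
#'   with identical rownames (sample ids).
#' @return Numeric matrix of width `sum of block widths`.
#' @export
assemble_meta_features <- function(blocks) {
  if (!length(blocks)) stop("need at least one meta-feature block")
  order_tags <- intersect(c("F", "Var", "RFECV"), names(blocks))
  if (length(order_tags) != length(blocks)) {
    stop("block names must be among F, Var, RFECV")
  }
  ids <- rownames(blocks[[1L]])
  for (b in blocks) {
    if (!identical(rownames(b), ids)) {
      stop("meta-feature blocks carry different sample ids or order")
    }
  }
  out <- do.call(cbind, lapply(order_tags, function(tag) {
    m <- blocks[[tag]]
    colnames(m) <- paste0(tag, ".", colnames(m))
    m
  }))
  rownames(out) <- ids
  out
}

#' Fit a meta-classifier on assembled meta-features
#'
#' @param meta_X Meta-feature matrix from [assemble_meta_features()].
#' @param y Binary labels aligned with `meta_X` rows.
#' @param meta Meta-classifier tag: `"RF"`, `"LR"` or `"SVM"`.
#' @param seed Integer seed.
#' @return List with the fitted model and a `prob(X)` closure.
#' @export
fit_meta <- function(meta_X, y, meta = c("RF", "LR", "SVM"), seed = 1L) {
  meta <- match.arg(meta)
  yf <- factor(y, levels = c(0, 1))
  # degenerate input: no meta-feature varies, so no classifier can do
  # better than the class prior (and tree backends cannot split at all) --
  # return an explicit constant model predicting the prior
  if (all(apply(meta_X, 2L, function(col) diff(range(col)) == 0))) {
    prior <- mean(y)
    return(list(meta = meta, model = NULL,
                prob = function(X) rep(prior, nrow(X)), seed = seed))
  }
  set.seed(seed)
  model <- switch(meta,
    RF = randomForest::randomForest(meta_X, yf, ntree = 300L),
    LR = {
      df <- data.frame(meta_X, .y = y)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    SVM = e1071::svm(meta_X, yf, kernel = "radial", probability = TRUE))
  prob <- switch(meta,
    RF = function(X) stats::predict(model, X, type = "prob")[, "1"],
    LR = function(X) {
      as.numeric(stats::predict(model, data.frame(X), type = "response"))
    },
    SVM = function(X) {
      p <- stats::predict(model, X, probability = TRUE)
      attr(p, "probabilities")[, "1"]
    })
  list(meta = meta, model = model, prob = prob, seed = seed)
}

#' Fit the two-layer stacked PVP classifier
#'
#' The one-call fitting interface. For each requested selector a feature
#' subset is fitted on the training data, a base layer is trained on the
#' reduced matrix, and the out-of-fold probability blocks are concatenated
#' into meta-features for the meta-classifier. The default — F-score and
#' RFECV blocks with a random-forest meta model — is the configuration that
#' performs best in the framework's experiment grid.
#'
#' @param fm A [feature_matrix()] of training samples (full feature space,
#'   e.g. the 860 evolutionary features).
#' @param selectors Character subset of `c("F", "Var", "RFECV")`.
#' @param meta Meta-classifier tag (`"RF"`, `"LR"`, `"SVM"`).
#' @param spec A [base_layer_spec()] shared by all blocks.
#' @param threshold Probability threshold for the positive class
#'   (default 0.5; a probability equal to the threshold is positive).
#' @param f_k Features kept by the F-score selector (default
#'   `min(400, d)`).
#' @param var_threshold Variance threshold (default: 25th percentile of the
#'   feature variances).
#' @param rfecv_args List of arguments for [rfecv_select()] (e.g.
#'   `list(step = 25, cv_folds = 5)`).
#' @param selections Optional named list of pre-fitted `pvp_selection`
#'   objects to use instead of fitting selectors here.
#' @return An object of class `pvp_stack`.
#' @seealso [predict.pvp_stack()], [enumerate_grid()], [run_grid()]
#' @export
pvp_stack <- function(fm, selectors = c("F", "RFECV"), meta = "RF",
                      spec = base_layer_spec(), threshold = 0.5,
                      f_k = NULL, var_threshold = NULL,
                      rfecv_args = list(), selections = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  selectors <- match.arg(selectors, c("F", "Var", "RFECV"), several.ok = TRUE)
  selectors <- intersect(c("F", "Var", "RFECV"), selectors)  # canonical order
  if (is.null(selections)) {
    selections <- list()
    for (s in selectors) {
      selections[[s]] <- switch(s,
        F = f_select(fm, k = f_k %||% min(400L, ncol(fm$X))),
        Var = variance_select(fm, threshold = var_threshold),
        RFECV = do.call(rfecv_select,
                        c(list(fm = fm, seed = spec$seed), rfecv_args)))
    }
  } else {
    if (!setequal(names(selections), selectors)) {
      stop("selections must be named exactly by the requested selectors")
    }
  }
  base_fits <- list()
  oof_blocks <- list()
  for (s in selectors) {
    reduced <- apply_selection(fm, selections[[s]])
    base_fits[[s]] <- fit_base_layer(reduced, spec)
    oof_blocks[[s]] <- base_fits[[s]]$oof
  }
  meta_X <- assemble_meta_features(oof_blocks)
  meta_fit <- fit_meta(meta_X, fm$y, meta, seed = spec$seed)
  structure(list(selectors = selectors, selections = selections,
                 base_fits = base_fits, meta_fit = meta_fit,
                 meta_features = meta_X, spec = spec, threshold = threshold,
                 ids = fm$ids, y = fm$y, n_features = ncol(fm$X)),
            class = "pvp_stack")
}

#' Predict PVP probabilities with a stacked model
#'
#' New samples pass through each block's stored selection and full-data base
#' refits, producing `length(algorithms) * length(selectors)` probabilities
#' per sample, which the meta-classifier maps to the final positive-class
#' probability. The label is positive when the probability is at least the
#' model's threshold.
#'
#' @param object A `pvp_stack` model.
#' @param newdata A [feature_matrix()] or numeric matrix containing the
#'   model's full feature space (columns matched by name).
#' @param ... Unused.
#' @return Data frame with columns `id`, `probability`, `label`.
#' @export
predict.pvp_stack <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$X else as.matrix(newdata)
  blocks <- list()
  for (s in object$selectors) {
    blocks[[s]] <- predict_base_layer(object$base_fits[[s]], X)
  }
  meta_X <- assemble_meta_features(blocks)
  prob <- object$meta_fit$prob(meta_X)
  prob <- pmin(pmax(as.numeric(prob), 0), 1)
  data.frame(id = rownames(X) %||% paste0("s", seq_len(nrow(X))),
             probability = prob,
             label = as.integer(prob >= object$threshold),
             stringsAsFactors = FALSE)
}

#' @export
print.pvp_stack <- function(x, ...) {
  cat("Stacked PVP classifier\n")
  cat("  meta-classifier : ", x$meta_fit$meta, "\n", sep = "")
  cat("  selector blocks : ", paste(x$selectors, collapse = " + "), "\n", sep = "")
  cat("  base algorithms : ", paste(x$spec$algorithms, collapse = ", "),
      "\n", sep = "")
  cat("  meta-feature width: ", ncol(x$meta_features), " (",
      length(x$spec$algorithms), " x ", length(x$selectors), ")\n", sep = "")
  cat("  training samples: ", length(x$y), " (", sum(x$y == 1L), " PVP)\n",
      sep = "")
  invisible(x)
}

#' @export
summary.pvp_stack <- function(object, ...) {
  oof_prob <- object$meta_fit$prob(object$meta_features)
  cc <- confusion(object$y, oof_prob, object$threshold)
  out <- list(model = object,
              kept = vapply(object$selections, function(s)
                length(s$kept_names), integer(1)),
              training_metrics = classification_metrics(cc),
              training_auc = roc_auc(object$y, oof_prob))
  class(out) <- "summary.pvp_stack"
  out
}

#' @export
print.summary.pvp_stack <- function(x, ...) {
  print(x$model)
  cat("  features kept per block: ",
      paste(names(x$kept), x$kept, sep = "=", collapse = ", "), "\n", sep = "")
  m <- x$training_metrics
  cat(sprintf("  apparent (meta-input) ACC %.4f  Sn %.4f  Sp %.4f  MCC %.4f  AUC %.4f\n",
              m["ACC"], m["Sn"], m["Sp"], m["MCC"], x$training_auc))
  invisible(x)
}

#' Enumerate the framework's experiment grid
#'
#' The full design: 12 base algorithms x 3 selector datasets = 36 base
#' models, and every non-empty subset of the three selector blocks (7) x 3
#' meta-classifiers = 21 stacked configurations.
#'
#' @return List with data frames `base` (36 rows: `algorithm`, `selector`)
#'   and `stacked` (21 rows: `combination`, `meta`).
#' @export
enumerate_grid <- function() {
  selectors <- c("F", "Var", "RFECV")
  base <- expand.grid(algorithm = all_algorithms(), selector = selectors,
                      stringsAsFactors = FALSE)
  combos <- unlist(lapply(1:3, function(k) {
    apply(utils::combn(selectors, k), 2L, paste, collapse = "_")
  }))
  stacked <- expand.grid(combination = combos, meta = c("LR", "RF", "SVM"),
                         stringsAsFactors = FALSE)
  list(base = base, stacked = stacked)
}

#' Run the stacked-model experiment grid on a train/test pair
#'
#' Fits the three selectors and three base layers once on the training data,
#' then evaluates every block combination under each meta-classifier on the
#' held-out data, mirroring the framework's 21-configuration comparison.
#' Also reports per-algorithm base-model test metrics for each selector
#' dataset.
#'
#' @param train,test [feature_matrix()] objects over the same feature space.
#' @param spec A [base_layer_spec()].
#' @param threshold Decision threshold (default 0.5).
#' @param f_k,var_threshold,rfecv_args Selector parameters as in
#'   [pvp_stack()].
#' @return List with data frames `stacked` (one row per meta/combination
#'   with the full metric suite) and `base` (one row per algorithm x
#'   selector).
#' @export
run_grid <- function(train, test, spec = base_layer_spec(), threshold = 0.5,
                     f_k = NULL, var_threshold = NULL, rfecv_args = list()) {
  selectors <- c("F", "Var", "RFECV")
  selections <- list(
    F = f_select(train, k = f_k %||% min(400L, ncol(train$X))),
    Var = variance_select(train, threshold = var_threshold),
    RFECV = do.call(rfecv_select,
                    c(list(fm = train, seed = spec$seed), rfecv_args)))
  base_fits <- list(); holdout_blocks <- list(); oof_blocks <- list()
  base_rows <- list()
  for (s in selectors) {
    reduced <- apply_selection(train, selections[[s]])
    base_fits[[s]] <- fit_base_layer(reduced, spec)
    oof_blocks[[s]] <- base_fits[[s]]$oof
    holdout_blocks[[s]] <- predict_base_layer(base_fits[[s]], test$X)
    for (tag in spec$algorithms) {
      p <- holdout_blocks[[s]][, tag]
      base_rows[[length(base_rows) + 1L]] <- cbind(
        data.frame(selector = s, algorithm = tag, stringsAsFactors = FALSE),
        metric_row(test$y, p, threshold))
    }
  }
  grid <- enumerate_grid()$stacked
  stacked_rows <- list()
  for (r in seq_len(nrow(grid))) {
    combo <- strsplit(grid$combination[r], "_", fixed = TRUE)[[1]]
    meta_train <- assemble_meta_features(oof_blocks[combo])
    meta_test <- assemble_meta_features(holdout_blocks[combo])
    mf <- fit_meta(meta_train, train$y, grid$meta[r], seed = spec$seed)
    p <- pmin(pmax(as.numeric(mf$prob(meta_test)), 0), 1)
    stacked_rows[[r]] <- cbind(
      data.frame(meta = grid$meta[r], combination = grid$combination[r],
                 stringsAsFactors = FALSE),
      metric_row(test$y, p, threshold))
  }
  list(stacked = do.call(rbind, stacked_rows),
       base = do.call(rbind, base_rows),
       selections = selections)
}

# one-row data frame with the full metric suite
metric_row <- function(y, prob, threshold) {
  cc <- confusion(y, prob, threshold)
  m <- suppressWarnings(classification_metrics(cc))
  data.frame(ACC = m["ACC"], Sn = m["Sn"], Sp = m["Sp"],
             Precision = m["Precision"], F1 = m["F1"], MCC = m["MCC"],
             AUC = roc_auc(y, prob), row.names = NULL)
}
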