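# Base-learner registry for the stacked ensemble.
#
# Twelve algorithm slots make up the full first-layer roster: DT, RF, EF,
# GBDT, XGBoost, LightGBM, AdaBoost, CatBoost, SVM, ANN, KNN, MLP. Ten have
# installed backends; LightGBM and CatBoost have no R backend in this
# package's dependency set, are reported as unavailable, and requesting them
# is an explicit error (never a silent skip). Hyperparameters default to
# each backend's documented defaults (with seeds pinned) and are overridable
# per algorithm through the spec's `params` list.

#' Tags of the full 12-algorithm first-layer roster
#' @return Character vector of 12 algorithm tags.
#' @export
all_algorithms <- function() {
  c("DT", "RF", "EF", "GBDT", "XGBoost", "LightGBM",
    "AdaBoost", "CatBoost", "SVM", "ANN", "KNN", "MLP")
}

#' Tags with an installed backend
#' @return Character vector of the algorithm tags that can be fitted.
#' @export
available_algorithms <- function() {
  setdiff(all_algorithms(), c("LightGBM", "CatBoost"))
}

#' @return list(fit = function(X, y, seed, params) model,
#'              prob = function(model, X) positive-class probability)
#' @noRd
learner_backend <- function(tag) {
  switch(tag,
    DT = list(
      fit = function(X, y, seed, params) {
        set.seed(seed)
        df <- data.frame(X, .y = factor(y, levels = c(0, 1)))
        do.call(rpart::rpart,
                merge_params(list(.y ~ ., data = df, method = "class"),
                             params))
      },
      prob = function(model, X) {
        stats::predict(model, data.frame(X), type = "prob")[, "1"]
      }),
    RF = list(
      fit = function(X, y, seed, params) {
        set.seed(seed)
        do.call(randomForest::randomForest,
                merge_params(list(x = X, y = factor(y, levels = c(0, 1)),
                                  ntree = 300L), params))
      },
      prob = function(model, X) stats::predict(model, X, type = "prob")[, "1"]),
    EF = list(
      fit = function(X, y, seed, params) {
        do.call(ranger::ranger,
                merge_params(list(x = X, y = factor(y, levels = c(0, 1)),
                                  num.trees = 300L, splitrule = "extratrees",
                                  probability = TRUE, seed = seed,
                                  num.threads = 1L), params))
      },
      prob = function(model, X) stats::predict(model, X)$predictions[, "1"]),
    GBDT = list(  # classic gradient-boosted trees: exact split finding
      fit = function(X, y, seed, params) {
        xgb_fit(X, y, seed,
                merge_params(list(eta = 0.1, max_depth = 3,
                                  tree_method = "exact"), params),
                nrounds = 100L)
      },
      prob = function(model, X) xgb_prob(model, X)),
    XGBoost = list(
      fit = function(X, y, seed, params) {
        xgb_fit(X, y, seed,
                merge_params(list(eta = 0.3, max_depth = 6,
                                  tree_method = "hist"), params),
                nrounds = 50L)
      },
      prob = function(model, X) xgb_prob(model, X)),
    AdaBoost = list(
      fit = function(X, y, seed, params) {
        set.seed(seed)
        do.call(adaboost_fit, merge_params(list(X = X, y = y), params))
      },
      prob = function(model, X) adaboost_prob(model, X)),
    SVM = list(
      fit = function(X, y, seed, params) {
        set.seed(seed)
        do.call(e1071::svm,
                merge_params(list(x = X, y = factor(y, levels = c(0, 1)),
                                  kernel = "radial", probability = TRUE),
                             params))
      },
      prob = function(model, X) {
        p <- stats::predict(model, X, probability = TRUE)
        attr(p, "probabilities")[, "1"]
      }),
    ANN = list(
      fit = function(X, y, seed, params) {
        set.seed(seed)
        do.call(nnet::nnet,
                merge_params(list(x = X, y = y, size = 8L, decay = 0.01,
                                  maxit = 200L, entropy = TRUE,
                                  trace = FALSE, MaxNWts = 100000L),
                             params))
      },
      prob = function(model, X) as.numeric(stats::predict(model, X))),
    KNN = list(
      fit = function(X, y, seed, params) {
        do.call(caret::knn3,
                merge_params(list(x = X, y = factor(y, levels = c(0, 1)),
                                  k = 5L), params))
      },
      prob = function(model, X) stats::predict(model, X, type = "prob")[, "1"]),
    MLP = list(  # wider, more regularized single-hidden-layer perceptron
      fit = function(X, y, seed, params) {
        set.seed(seed)
        do.call(nnet::nnet,
                merge_params(list(x = X, y = y, size = 16L, decay = 0.1,
                                  maxit = 300L, entropy = TRUE,
                                  trace = FALSE, MaxNWts = 100000L),
                             params))
      },
      prob = function(model, X) as.numeric(stats::predict(model, X))),
    stop("no backend installed for algorithm tag: ", tag)
  )
}

xgb_fit <- function(X, y, seed, params, nrounds) {
  nr <- params$nrounds %||% nrounds
  params$nrounds <- NULL
  xgboost::xgb.train(
    params = c(list(objective = "binary:logistic", nthread = 1L,
                    seed = seed), params),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
    nrounds = nr, verbose = 0)
}

xgb_prob <- function(model, X) {
  stats::predict(model, xgboost::xgb.DMatrix(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# backend defaults overridden by user-supplied hyperparameters
merge_params <- function(defaults, params) {
  if (!length(params)) return(defaults)
  utils::modifyList(defaults, params)
}

# ---- AdaBoost (discrete SAMME with shallow rpart trees) ------------------
# No AdaBoost implementation ships with the installed dependency set, so the
# classic reweighting algorithm is implemented here: M rounds of
# depth-limited trees on weighted data; round weight
# alpha = log((1 - err) / err); class scores are the alpha-weighted votes
# and probabilities their softmax.

adaboost_fit <- function(X, y, n_rounds = 50L, maxdepth = 2L) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  yf <- factor(y, levels = c(0, 1))
  df <- data.frame(X, .y = yf)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, minsplit = 2L,
                          xval = 0L))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != yf)) / sum(w)
    if (err >= 0.5) break                       # weak-learner assumption gone
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != yf))
    w <- w / sum(w)
    if (err <= 1e-10) break                     # perfect fit; votes saturated
  }
  if (!length(stumps)) {                        # no usable weak learner
    stumps <- list(NULL)
    alphas <- 0
  }
  structure(list(trees = stumps, alphas = alphas,
                 base_rate = mean(y)), class = "pvp_adaboost")
}

adaboost_prob <- function(model, X) {
  df <- data.frame(X)
  n <- nrow(df)
  score <- numeric(n)                           # sum alpha * (+1 pos / -1 neg)
  total <- sum(model$alphas)
  if (total == 0) return(rep(model$base_rate, n))
  for (m in seq_along(model$trees)) {
    if (is.null(model$trees[[m]])) next
    pred <- stats::predict(model$trees[[m]], df, type = "class")
    score <- score + model$alphas[m] * ifelse(pred == "1", 1, -1)
  }
  1 / (1 + exp(-score))                         # logistic squash of the margin
}

# ---- fold utilities ------------------------------------------------------

#' Stratified fold assignment
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, class proportions balanced
#'   across folds.
#' @export
stratified_folds <- function(y, k, seed) {
  if (k < 2L) stop("need at least 2 folds")
  if (length(y) < k) stop("n must be at least the number of folds")
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    rows <- which(y == cls)
    folds[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  folds
}
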